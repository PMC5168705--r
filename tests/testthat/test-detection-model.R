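test_that("the fixed published model evaluates its printed equation", {
    m <- fixedPublishedModel()
    zeros <- c(RASGRF1 = 0, CPXM1 = 0, HOXA10 = 0, DACH1 = 0,
               Mean12 = 0, IC = 0)
    expect_equal(detectionIndex(m, zeros), -6.98073)
    ## all-ones: the hand sum of the printed coefficients plus intercept
    handSum <- 0.62449 + 0.78110 + 0.12115 + 0.36760 + 0.65288 + 2.44704 -
        6.98073
    expect_equal(detectionIndex(m, zeros + 1), handSum)
    expect_equal(unname(coef(m)),
                 c(0.62449, 0.78110, 0.12115, 0.36760, 0.65288, 2.44704))
    expect_equal(modelIntercept(m), -6.98073)
    expect_equal(decisionCutoff(m), -0.07923)
})

test_that("classification is strict at the cutoff", {
    expect_equal(classifyIndex(-0.07923), "negative")
    expect_equal(classifyIndex(-0.07923 + 1e-9), "positive")
    expect_equal(classifyIndex(0), "positive")
    expect_equal(classifyIndex(-10), "negative")
})

test_that("detection index handles empty models and missing variables", {
    const <- LinearDetectionModel(character(0), numeric(0), 3.5)
    expect_equal(detectionIndex(const, data.frame(x = c(1, 2))), c(3.5, 3.5))
    m <- fixedPublishedModel()
    expect_error(detectionIndex(m, data.frame(RASGRF1 = 1)), "lacks")
})

test_that("detection index is monotone in each positively weighted variable", {
    m <- fixedPublishedModel()
    set.seed(6)
    base <- as.data.frame(as.list(stats::setNames(rnorm(6),
                                                  variableNames(m))))
    for (v in variableNames(m)) {
        bumped <- base
        bumped[[v]] <- bumped[[v]] + abs(rnorm(1)) + 0.1
        expect_gt(detectionIndex(m, bumped), detectionIndex(m, base))
    }
})

test_that("linear SVM orients toward the positive class and reproduces
           its own decision values", {
    sim <- makeFeatureSim(n = 40, shift = 3, seed = 2)
    fit <- fitLinearSVM(sim$features, sim$labels)
    ## signal variables pull toward BC
    expect_true(all(coef(fit)[c("RASGRF1", "CPXM1", "IC")] > 0))
    ## internal consistency: decision values == detection index exactly
    x <- as.matrix(sim$features)
    raw <- e1071::svm(x, factor(sim$labels, levels = c("HV", "BC")),
                      type = "C-classification", kernel = "linear",
                      cost = 1, scale = FALSE)
    dv <- attr(predict(raw, x, decision.values = TRUE), "decision.values")
    sgn <- if (startsWith(colnames(dv), "BC")) 1 else -1
    expect_equal(unname(detectionIndex(fit, sim$features)),
                 unname(sgn * drop(dv)), tolerance = 1e-10)
})

test_that("flipping the class labels negates the weights", {
    sim <- makeFeatureSim(n = 30, shift = 2, seed = 3)
    f1 <- fitLinearSVM(sim$features, sim$labels, positive = "BC")
    flipped <- ifelse(sim$labels == "BC", "HV", "BC")
    f2 <- fitLinearSVM(sim$features, flipped, positive = "BC")
    expect_equal(unname(coef(f2)), -unname(coef(f1)), tolerance = 1e-8)
    expect_equal(modelIntercept(f2), -modelIntercept(f1), tolerance = 1e-8)
    expect_error(fitLinearSVM(sim$features, rep("BC", 30)), "both classes")
})

test_that("LOOCV equals the naive per-sample refit loop", {
    sim <- makeFeatureSim(n = 16, shift = 1.5, seed = 4)
    got <- loocvScores(sim$features, sim$labels)
    naive <- vapply(seq_len(16), function(i) {
        m <- fitLinearSVM(sim$features[-i, ], sim$labels[-i])
        detectionIndex(m, sim$features[i, , drop = FALSE])
    }, numeric(1))
    expect_identical(got, unname(naive))
    ## perfectly separable toy data scores LOOCV AUC 1
    sep <- makeFeatureSim(n = 12, shift = 10, seed = 5)
    expect_equal(rocAuc(loocvScores(sep$features, sep$labels), sep$labels),
                 1.0)
    expect_error(loocvScores(sim$features[1:5, ], sim$labels[1:5]),
                 "3 samples")
})

test_that("label-independent features give chance-level LOOCV AUC", {
    set.seed(8)
    n <- 80
    x <- data.frame(a = rnorm(n), b = rnorm(n))
    labels <- rep(c("HV", "BC"), n / 2)
    auc <- rocAuc(loocvScores(x, labels), labels)
    expect_lt(abs(auc - 0.5), 3 * sqrt(0.25 * (1 / 40 + 1 / 40)) + 0.05)
})

test_that("mask enumeration covers every nonempty subset", {
    expect_equal(nrow(enumerateVariableMasks(1)), 1)
    m3 <- enumerateVariableMasks(3)
    expect_equal(nrow(m3), 7)
    expect_equal(anyDuplicated(apply(m3, 1, paste, collapse = "")), 0)
    for (v in c(2, 5, 8, 11, 15))
        expect_equal(nrow(enumerateVariableMasks(v)), 2^v - 1)
})

test_that("exhaustive search at V=3 matches an independent brute-force scan", {
    sim <- makeFeatureSim(n = 24, signalVars = c("A", "B"),
                          noiseVars = "C", shift = 2, seed = 9)
    sr <- exhaustiveSearch(sim$features, sim$labels,
                           variables = c("A", "B", "C"))
    tab <- searchTable(sr)
    expect_equal(nrow(tab), 7)
    ## oracle: enumerate subsets with combn, score by pooled LOOCV AUC
    oracle <- list()
    for (k in 1:3) {
        for (ix in asplit(combn(3, k), 2)) {
            vars <- c("A", "B", "C")[ix]
            auc <- rocAuc(loocvScores(sim$features[, vars, drop = FALSE],
                                      sim$labels), sim$labels)
            oracle[[paste(vars, collapse = "+")]] <- auc
        }
    }
    tabKeys <- character(nrow(tab))
    for (r in seq_len(nrow(tab))) {
        vars <- c("A", "B", "C")[strsplit(tab$mask[r], "")[[1]] == "1"]
        tabKeys[r] <- paste(vars, collapse = "+")
        expect_equal(tab$loocvAUC[r], oracle[[tabKeys[r]]])
    }
    ## the winner is the all-positive subset with the top oracle AUC
    bestOracle <- max(unlist(oracle[tabKeys[tab$allWeightsPositive]]))
    expect_equal(sr@bestLoocvAUC, bestOracle)
})

test_that("search ties prefer fewer variables and flag constraint failure", {
    set.seed(10)
    n <- 20
    x <- data.frame(A = rnorm(n) + rep(c(0, 4), each = n / 2))
    x$B <- x$A  # duplicated variable: identical AUC for {A}, {B}, {A,B}
    labels <- rep(c("HV", "BC"), each = n / 2)
    sr <- exhaustiveSearch(x, labels, variables = c("A", "B"))
    expect_length(variableNames(bestModel(sr)), 1)

    ## a variable pointing the wrong way cannot satisfy the constraint
    neg <- data.frame(A = rnorm(n) - rep(c(0, 4), each = n / 2))
    expect_warning(srNeg <- exhaustiveSearch(neg, labels, variables = "A"),
                   "unconstrained")
    expect_false(srNeg@constraintSatisfied)
    expect_lt(coef(bestModel(srNeg))["A"], 0)
})

test_that("search recovers the signal-carrying variables", {
    ## only RASGRF1, CPXM1 and IC carry class signal among six searched
    ## variables; the winner must contain all three in >= 90% of replicates
    ## n = 100 per replicate: best-subset selection by LOOCV AUC needs the
    ## AUC-difference noise well below each variable's marginal contribution
    hits <- 0
    for (rep in 1:20) {
        sim <- makeFeatureSim(n = 100, shift = 1.2, seed = 100 + rep)
        sr <- exhaustiveSearch(sim$features, sim$labels,
                               variables = colnames(sim$features))
        if (all(c("RASGRF1", "CPXM1", "IC") %in%
                    variableNames(bestModel(sr))))
            hits <- hits + 1
    }
    expect_gte(hits, 18)
})

test_that("classification of a cohort is invariant to processing order", {
    sim <- makeFeatureSim(n = 20, seed = 11)
    colnames(sim$features) <- variableNames(fixedPublishedModel())
    idx <- detectionIndex(fixedPublishedModel(), sim$features)
    calls <- classifyIndex(idx)
    perm <- sample(20)
    idxPerm <- detectionIndex(fixedPublishedModel(), sim$features[perm, ])
    expect_identical(classifyIndex(idxPerm), calls[perm])
})
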