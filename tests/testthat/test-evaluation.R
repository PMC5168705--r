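test_that("rank AUC matches exhaustive pair counting with ties at 1/2", {
    expect_equal(rocAuc(c(1, 2, 3, 4), c("HV", "HV", "BC", "BC")), 1)
    expect_equal(rocAuc(rep(2, 6), rep(c("HV", "BC"), 3)), 0.5)
    set.seed(13)
    for (rep in 1:5) {
        scores <- sample(1:6, 12, replace = TRUE)  # force ties
        labels <- sample(rep(c("HV", "BC"), 6))
        got <- rocAuc(scores, labels)
        pos <- scores[labels == "BC"]; neg <- scores[labels == "HV"]
        pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
        expect_equal(got, mean(pairs))
        ## antisymmetry up to tie handling
        expect_equal(rocAuc(-scores, labels), 1 - got)
    }
    expect_error(rocAuc(1:3, rep("BC", 3)), "both classes")
    ## independent library cross-check
    if (requireNamespace("pROC", quietly = TRUE)) {
        set.seed(29)
        scores <- rnorm(30); labels <- sample(rep(c("HV", "BC"), 15))
        expect_equal(rocAuc(scores, labels),
                     as.numeric(pROC::auc(pROC::roc(
                         labels, scores, levels = c("HV", "BC"),
                         direction = "<", quiet = TRUE))))
    }
})

test_that("confusion metrics recompute from their own counts", {
    ## 2x2 table {TP=9, FN=1, TN=8, FP=2}
    scores <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)
    labels <- rep(c("BC", "HV"), c(10, 10))
    cm <- confusionAtCutoff(scores, labels, cutoff = 0)
    expect_equal(cm[c("tp", "fn", "tn", "fp")],
                 list(tp = 9, fn = 1, tn = 8, fp = 2))
    expect_equal(cm$sensitivity, 0.9)
    expect_equal(cm$specificity, 0.8)
    expect_equal(cm$ppv, 9 / 11)
    expect_equal(cm$npv, 8 / 9)
    expect_equal(cm$accuracy, 17 / 20)
    expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, 20)

    ## cutoff above every score: nothing called positive
    hi <- confusionAtCutoff(scores, labels, cutoff = 10)
    expect_equal(hi$sensitivity, 0)
    expect_equal(hi$specificity, 1)
    ## perfect separation: all metrics 1
    perfect <- confusionAtCutoff(c(1, 1, -1, -1), c("BC", "BC", "HV", "HV"),
                                 cutoff = 0)
    expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                     "npv", "accuracy")]) == 1))
})

test_that("ROC points span both endpoints and integrate to the AUC", {
    set.seed(31)
    scores <- rnorm(24)  # tie-free
    labels <- sample(rep(c("HV", "BC"), 12))
    pts <- rocPoints(scores, labels)
    expect_equal(pts$sensitivity[1], 1)
    expect_equal(pts$specificity[1], 0)
    expect_equal(pts$sensitivity[nrow(pts)], 0)
    expect_equal(pts$specificity[nrow(pts)], 1)
    expect_true(all(diff(pts$sensitivity) <= 0))
    expect_true(all(diff(pts$specificity) >= 0))
    ## trapezoidal area under the curve equals the rank AUC (no ties)
    fpr <- rev(1 - pts$specificity); tpr <- rev(pts$sensitivity)
    area <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
    expect_equal(area, rocAuc(scores, labels))
})

test_that("stratified split reproduces the published train/validation sizes", {
    roster <- simulateRoster(cohortPreset("table1_cohort", seed = 5))
    split <- stratifiedSplit(roster, table1SplitFractions(), seed = 5)
    expect_equal(sum(split$split == "train"), 167)
    expect_equal(sum(split$split == "validation"), 111)
    ## per-stratum counts match the published table
    tr <- split[split$split == "train", ]
    expect_equal(sum(tr$class == "HV"), 80)
    expect_equal(sum(tr$class == "BC"), 87)
    expect_equal(as.integer(table(tr$stage[tr$class == "BC"])
                            [c("0", "I", "IIA", "IIB", "III", "IV")]),
                 c(3L, 27L, 19L, 11L, 8L, 19L))
    ## deterministic under the same seed
    split2 <- stratifiedSplit(roster, table1SplitFractions(), seed = 5)
    expect_identical(split$split, split2$split)
    ## different seed reshuffles within strata but keeps the counts
    split3 <- stratifiedSplit(roster, table1SplitFractions(), seed = 6)
    expect_equal(sum(split3$split == "train"), 167)
    expect_false(identical(split$split, split3$split))
})

test_that("split edge cases: full training and singleton strata", {
    roster <- simulateRoster(cohortSimConfig(
        nHv = 5, nBc = 5,
        stageDist = c("0" = 0, I = 1, IIA = 0, IIB = 0, III = 0, IV = 0),
        dcisStagePairing = FALSE, seed = 1))
    all_train <- stratifiedSplit(roster, 1, seed = 1)
    expect_true(all(all_train$split == "train"))
    tiny <- simulateRoster(cohortSimConfig(
        nHv = 3, nBc = 1,
        stageDist = c("0" = 0, I = 1, IIA = 0, IIB = 0, III = 0, IV = 0),
        dcisStagePairing = FALSE, seed = 1))
    expect_warning(s <- stratifiedSplit(tiny, 0.5, seed = 1), "single sample")
    expect_equal(s$split[s$class == "BC"], "train")
})

test_that("Jonckheere-Terpstra matches exact enumeration on small data", {
    ## strictly increasing singletons: the most extreme of 3! arrangements
    jt <- jonckheereTerpstra(c(1, 2, 3), factor(c("a", "b", "c")),
                             exact = TRUE)
    expect_equal(jt$statistic, 3)
    expect_equal(jt$p.value, 1 / 6)
    ## all identical values: statistic at the null mean, p near 1
    flat <- jonckheereTerpstra(rep(1, 9), factor(rep(c("a", "b", "c"), 3)),
                               exact = FALSE)
    expect_equal(flat$statistic, (81 - 27) / 4)
    expect_gt(flat$p.value, 0.5)
    ## reversing the group order reflects the one-sided exact p value
    x <- c(1.2, 0.8, 2.1, 1.7, 3.0, 2.4)
    g <- factor(rep(c("a", "b", "c"), each = 2), levels = c("a", "b", "c"))
    gRev <- factor(g, levels = c("c", "b", "a"))
    pUp <- jonckheereTerpstra(x, g, exact = TRUE)$p.value
    pRevDown <- jonckheereTerpstra(x, gRev, alternative = "decreasing",
                                   exact = TRUE)$p.value
    expect_equal(pUp, pRevDown)
    expect_error(jonckheereTerpstra(1:4, factor(rep("a", 4))), "two")
})

test_that("JT normal approximation tracks the exact p within 0.02", {
    set.seed(17)
    for (rep in 1:4) {
        x <- rnorm(12)  # continuous: no ties
        g <- factor(rep(c("a", "b", "c"), each = 4))
        x[g == "b"] <- x[g == "b"] + rep * 0.3
        x[g == "c"] <- x[g == "c"] + rep * 0.6
        pExact <- jonckheereTerpstra(x, g, exact = TRUE)$p.value
        pNorm <- jonckheereTerpstra(x, g, exact = FALSE)$p.value
        expect_lt(abs(pExact - pNorm), 0.02)
    }
})

test_that("subgroup report covers stages, subtypes, trend and age", {
    set.seed(19)
    roster <- simulateRoster(cohortPreset("toy", seed = 19))
    ## scores: all BC above cutoff, HV below; index rises with stage
    stageLift <- c(none = 0, "0" = 1, I = 1.2, IIA = 1.5, IIB = 1.8,
                   III = 2.2, IV = 3)
    scores <- ifelse(roster$class == "BC", 1, -1) +
        stageLift[roster$stage] + rnorm(nrow(roster), 0, 0.05)
    rep <- subgroupReport(scores, roster, cutoff = 0)
    expect_true(all(rep$byStage$sensitivity == 1))
    expect_true(all(rep$byStage$auc == 1))
    expect_setequal(rep$byStage$bucket, c("0-I", "IIA", "IIB-III", "MBC"))
    expect_lt(rep$trendTest$p.value, 0.01)
    expect_true(!is.null(rep$subtypeTest))
    expect_true(abs(rep$ageCorrelation$r) <= 1)

    ## empty bucket is emitted with n = 0 and NA metrics
    noMBC <- roster[!(roster$class == "BC" & roster$stage == "IV"), ]
    rep2 <- subgroupReport(scores[!(roster$class == "BC" &
                                        roster$stage == "IV")], noMBC,
                           cutoff = 0)
    mbcRow <- rep2$byStage[rep2$byStage$bucket == "MBC", ]
    expect_equal(mbcRow$n, 0)
    expect_true(is.na(mbcRow$auc))
})

test_that("age shows no spurious correlation under the null", {
    ## age is independent of the detection index by construction; the
    ## Pearson test should stay non-significant in >= 90% of replicates
    calm <- 0
    nRep <- 40
    for (r in seq_len(nRep)) {
        set.seed(300 + r)
        roster <- data.frame(class = rep("BC", 100),
                             stage = sample(c("I", "IIA"), 100, TRUE),
                             subtype = "luminal",
                             age = round(runif(100, 36, 81)))
        scores <- rnorm(100)
        rep <- subgroupReport(scores, roster)
        if (rep$ageCorrelation$p > 0.05) calm <- calm + 1
    }
    expect_gte(calm / nRep, 0.9)
})

test_that("evaluation report is internally consistent", {
    set.seed(23)
    roster <- simulateRoster(cohortPreset("toy", seed = 23))
    scores <- ifelse(roster$class == "BC", 0.8, -0.8) + rnorm(60, 0, 0.6)
    er <- evaluationReport(scores, roster, cutoff = 0)
    with(er$confusion, {
        expect_equal(er$sensitivity, tp / (tp + fn))
        expect_equal(er$specificity, tn / (tn + fp))
        expect_equal(er$accuracy, (tp + tn) / 60)
    })
    expect_equal(er$auc, rocAuc(scores, roster$class))
})
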