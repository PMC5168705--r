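test_that("positive droplets are counted over the half-open interval", {
    thr <- AmplitudeThresholds(2, 6)
    expect_equal(countPositiveDroplets(c(1, 5, 9), thr), 1)
    expect_equal(countPositiveDroplets(c(0.5, 1, 1.5), thr), 0)
    ## boundary semantics: exactly at lower -> negative, at upper -> positive
    expect_equal(countPositiveDroplets(c(2, 6), thr), 1)
    expect_error(AmplitudeThresholds(6, 2), "lower")
})

test_that("Poisson correction inverts the zero class and scales volumes", {
    expect_equal(poissonConcentration(0, 1000)$lambda, 0)
    expect_equal(poissonConcentration(0, 1000)$concentration, 0)
    ## zero-class inversion: nPos/nTotal = 1 - e^-1 gives lambda = 1
    expect_equal(poissonConcentration((1 - exp(-1)) * 5000, 5000)$lambda, 1)
    ## hand-computed chain at default volumes
    q <- poissonConcentration(100, 10000)
    lam <- -log(1 - 100 / 10000)
    expect_equal(q$lambda, lam)
    expect_equal(q$copiesPerReaction, lam * 10000)
    expect_equal(q$copiesPerUlReaction, lam / (0.85e-3))
    expect_equal(q$concentration, lam * 10000 * (20 / 2) / 0.9)
})

test_that("Poisson correction is strictly increasing in the positive count", {
    conc <- vapply(0:99, function(np)
        poissonConcentration(np, 100)$concentration, numeric(1))
    expect_true(all(diff(conc) > 0))
})

test_that("saturated and empty wells are rejected unless corrected", {
    expect_error(poissonConcentration(100, 100), "saturated")
    expect_error(poissonConcentration(5, 0), "nTotal")
    expect_error(poissonConcentration(-1, 10), "nPos")
    q <- poissonConcentration(100, 100, continuityCorrection = TRUE)
    expect_equal(q$lambda, -log(1 - 99.5 / 100))
})

test_that("lambda recovery is within 5% for lambda in 1e-3..1", {
    ## droplet-level oracle: wells partitioned under Poisson statistics,
    ## counted at fixed between-cluster thresholds, Poisson-corrected back
    set.seed(101)
    nWells <- 200; nDroplets <- 12000
    thr <- AmplitudeThresholds(1500, 10000)
    for (lambda in c(0.001, 0.01, 0.1, 1)) {
        est <- vapply(seq_len(nWells), function(i) {
            nPos <- rbinom(1, nDroplets, 1 - exp(-lambda))
            amp <- c(rnorm(nPos, 8000, 300),
                     rnorm(nDroplets - nPos, 1000, 100))
            poissonConcentration(countPositiveDroplets(amp, thr),
                                 nDroplets)$lambda
        }, numeric(1))
        expect_lt(abs(median(est) - lambda) / lambda, 0.05)
    }
})

test_that("threshold search achieves AUC 1 on perfectly separated wells", {
    sim <- makeWellSim(nPosPerWell = c(rep(0, 6), rep(60, 6)),
                       labels = rep(c("HV", "BC"), each = 6), seed = 3)
    th <- optimizeAmplitudeThresholds(sim$droplets, "M1", sim$labels)
    expect_equal(th@achievedAUC, 1.0)
    ## the interval sits below the positive cluster and covers it: each BC
    ## well recovers (nearly) all of its 60 planted positives
    expect_lt(th@lower, 7000)
    dt <- dropletTable(sim$droplets)
    bcCounts <- vapply(sprintf("W%03d", 7:12), function(s)
        countPositiveDroplets(dt$amplitude[dt$sample_id == s], th),
        numeric(1))
    expect_true(all(bcCounts >= 55))
})

test_that("a single-pair grid is returned regardless of its AUC", {
    sim <- makeWellSim(nPosPerWell = c(0, 0, 0, 50, 50, 50),
                       labels = c("BC", "BC", "BC", "HV", "HV", "HV"),
                       seed = 4)
    th <- optimizeAmplitudeThresholds(sim$droplets, "M1", sim$labels,
                                      nGrid = 2)
    amp <- dropletTable(sim$droplets)$amplitude
    expect_equal(th@lower, min(amp))
    expect_equal(th@upper, max(amp))
})

test_that("degenerate identical amplitudes yield a warning", {
    dt <- data.frame(sample_id = rep(c("a", "b"), each = 10), marker = "M1",
                     well = "A01", channel = "FAM", amplitude = 5)
    dd <- DropletData(dt)
    expect_warning(
        th <- optimizeAmplitudeThresholds(dd, "M1",
                                          c(a = "HV", b = "BC")),
        "identical")
    expect_true(is.na(th@achievedAUC))
})

test_that("randomly permuted labels give chance-level achieved AUC", {
    set.seed(77)
    sim <- makeWellSim(nPosPerWell = rpois(40, 30),
                       labels = rep(c("HV", "BC"), 20), seed = 7)
    perm <- sample(unname(sim$labels))
    th <- optimizeAmplitudeThresholds(sim$droplets, "M1",
                                      stats::setNames(perm,
                                                      names(sim$labels)))
    ## 3 SE band around chance for n = 20/20
    se <- sqrt(0.5 * 0.5 * (1 / 20 + 1 / 20))
    expect_lt(abs(th@achievedAUC - 0.5), 3 * se + 0.05)
})

test_that("threshold search is invariant under monotone amplitude rescaling", {
    sim <- makeWellSim(nPosPerWell = c(rep(2, 5), rep(40, 5)),
                       labels = rep(c("HV", "BC"), each = 5), seed = 12)
    th1 <- optimizeAmplitudeThresholds(sim$droplets, "M1", sim$labels)
    dt <- dropletTable(sim$droplets)
    dt$amplitude <- (dt$amplitude / 1000)^1.7  # strictly monotone map
    th2 <- optimizeAmplitudeThresholds(DropletData(dt), "M1", sim$labels)
    expect_equal(th2@achievedAUC, th1@achievedAUC)
    expect_equal(th2@lower, (th1@lower / 1000)^1.7)
    expect_equal(th2@upper, (th1@upper / 1000)^1.7)
})

test_that("threshold search demands two classes", {
    sim <- makeWellSim(nPosPerWell = c(0, 10), labels = c("HV", "HV"))
    expect_error(optimizeAmplitudeThresholds(sim$droplets, "M1",
                                             sim$labels), "both classes")
})

test_that("marker cutoff maximises Youden J with the lowest-midpoint rule", {
    ## separable: lowest optimal midpoint
    cut <- determineMarkerCutoff(c(0, 0, 0, 1000, 1000),
                                 c("HV", "HV", "HV", "BC", "BC"))
    expect_equal(cut$cutoff, 500)
    expect_equal(cut$youdenJ, 1)
    ## identical concentrations: non-informative
    expect_warning(
        flat <- determineMarkerCutoff(rep(5, 6), rep(c("HV", "BC"), 3)),
        "non-informative")
    expect_false(flat$informative)
    expect_equal(flat$youdenJ, 0)
    expect_error(determineMarkerCutoff(1:3, rep("HV", 3)), "both classes")
})

test_that("cutoff search equals an exhaustive midpoint scan", {
    set.seed(9)
    for (rep in 1:5) {
        conc <- round(rexp(20, 0.01))
        labels <- sample(rep(c("HV", "BC"), 10))
        got <- determineMarkerCutoff(conc, labels)
        y <- labels == "BC"
        u <- sort(unique(conc))
        cand <- if (length(u) == 1) u else (head(u, -1) + u[-1]) / 2
        J <- vapply(cand, function(ct)
            mean(conc[y] > ct) + mean(conc[!y] <= ct) - 1, numeric(1))
        expect_equal(got$youdenJ, max(J))
        expect_equal(got$cutoff, cand[which.max(J)])
    }
})

test_that("quantification recovers manifest concentrations on the cohort", {
    ## full-scale cohort at default noise; thresholds and cutoffs trained on
    ## the training split only, validation quantified with trained values
    ccfg <- cohortPreset("table1_cohort", seed = 1)
    ccfg$nDroplets <- 4000
    roster <- simulateRoster(ccfg)
    sim <- simulateDroplets(roster, MarkerPanel(), ccfg)
    roster <- stratifiedSplit(roster, table1SplitFractions(), seed = 1)
    labels <- stats::setNames(roster$class, roster$sample_id)
    trainIds <- roster$sample_id[roster$split == "train"]
    dt <- dropletTable(sim$droplets)
    trainDrop <- DropletData(dt[dt$sample_id %in% trainIds, ],
                             dropletVolumes(sim$droplets))
    st <- trainQuantification(trainDrop, labels[trainIds])
    quants <- quantifyMarkers(sim$droplets, st$thresholds, st$cutoffs,
                              continuityCorrection = TRUE)
    mrg <- merge(quants, sim$manifest, by = c("sample_id", "marker"))
    rho <- cor(mrg$concentration, mrg$true_concentration,
               method = "spearman")
    expect_gt(rho, 0.95)
    ## positivity calls follow the strict concentration rule
    expect_identical(mrg$positive_call,
                     mrg$concentration > mrg$cutoff_used)
    rm(sim, dt, trainDrop, quants, mrg); gc(verbose = FALSE)
})
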