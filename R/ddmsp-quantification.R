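## Absolute quantification of ddMSP reactions.
##
## A droplet is positive when its amplitude falls in the half-open interval
## (lower, upper]. The thresholds per marker are chosen supervised: over a
## grid of pooled-amplitude quantiles, the (lower, upper] pair maximising the
## Mann-Whitney AUC of per-sample positive fractions against the HV/BC label
## is retained. Positive counts are Poisson-corrected to mean copies per
## droplet, then scaled through the volume chain to copies/ml plasma.

## Hanley-McNeil standard error of an AUC estimate
.hanleyMcNeilSE <- function(a, n1, n0) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
             (n1 * n0))
}

## counts of amplitudes <= each grid point, per sample (samples x grid)
.cumCountsAtGrid <- function(amps_by_sample, grid) {
    t(vapply(amps_by_sample,
             function(a) findInterval(grid, sort(a)),
             numeric(length(grid))))
}

#' Optimise droplet amplitude thresholds for one marker
#'
#' Builds a candidate grid from type-1 (inverse-ECDF) quantiles of the pooled
#' training amplitudes and evaluates every `(lower, upper]` grid pair by the
#' AUC of per-sample positive-droplet fractions against the class labels.
#' The positive fraction is a strictly monotone transform of the Poisson
#' concentration estimate, so this AUC is identical to the AUC of
#' concentrations; using quantiles makes the result invariant under monotone
#' amplitude rescaling.
#'
#' Because thousands of correlated candidate pairs are compared on a finite
#' training set, the raw argmax is subject to selection noise (an interval
#' slicing part of the positive cluster can beat the full cluster by luck),
#' and the AUC itself cannot see thresholds that add a near-constant
#' negative-cluster count to every sample (a constant shift leaves ranks
#' unchanged). The search therefore proceeds in two stages: (1) pairs within
#' three Hanley-McNeil standard errors of the maximum AUC are treated as
#' statistically indistinguishable (the allowance approximates the
#' selection inflation of a maximum over many correlated candidates); (2)
#' among them, the pair maximising the penalised separation
#' `delta - backgroundPenalty * negMed` wins, where `delta` is the
#' difference in class-median positive fractions and `negMed` the
#' negative-class median fraction (medians, because the biological
#' concentration spread is heavy-tailed and the criterion must share the
#' rank-based AUC's outlier robustness). The penalty term strictly rejects
#' any interval dipping into the negative cluster or the rain (which adds
#' background but no separation), while intervals that merely thin the
#' positive cluster score a strictly smaller `delta` on the same droplets
#' and lose too. Residual exact ties resolve to smallest `lower`, then
#' largest `upper`. The reported `achievedAUC` is the chosen pair's AUC.
#'
#' @param dropletData a [DropletData-class] restricted (or restrictable) to
#'   training samples; only rows for `marker` are used.
#' @param marker marker identifier to optimise.
#' @param labels named character/factor of HV/BC labels, names = sample ids
#'   (or a vector aligned with the per-sample order of unique sample ids).
#' @param nGrid number of quantile grid points (default 64).
#' @param positive label treated as the positive class.
#' @param backgroundPenalty weight of the negative-class mean fraction in
#'   the stage-2 criterion; must be smaller than the weakest usable
#'   marker's class fold-change minus one (default 0.15).
#' @return An [AmplitudeThresholds-class] with the achieved AUC.
#' @export
optimizeAmplitudeThresholds <- function(dropletData, marker, labels,
                                        nGrid = 64, positive = "BC",
                                        backgroundPenalty = 0.15) {
    dt <- dropletTable(dropletData)
    dt <- dt[dt$marker == marker, ]
    if (nrow(dt) == 0) stop("no droplets for marker ", marker)
    amps <- split(dt$amplitude, dt$sample_id)
    if (!is.null(names(labels))) labels <- labels[names(amps)]
    labels <- as.character(labels)
    if (length(labels) != length(amps) || anyNA(labels))
        stop("labels must cover every sample with droplets")
    if (length(unique(labels)) < 2)
        stop("both classes are required to optimise thresholds")
    pooled <- dt$amplitude
    ## Probability ladder: half the points evenly spaced, half with 1-p
    ## log-spaced down to 1e-5. Positive droplets can be anywhere from ~10%
    ## to ~1e-4 of partitions depending on template load, so the informative
    ## cuts live in upper quantiles spanning several orders of magnitude of
    ## tail mass; type-1 quantiles keep the grid an order statistic
    ## (invariant under monotone amplitude rescaling).
    nHalf <- floor(nGrid / 2)
    probs <- sort(unique(c(seq(0, 0.9, length.out = nHalf),
                           1 - 10^seq(log10(0.1), log10(1e-5),
                                      length.out = nGrid - nHalf - 1),
                           1)))
    grid <- unique(quantile(pooled, probs = probs, type = 1, names = FALSE))
    if (length(grid) < 2) {
        warning("all amplitudes identical; degenerate thresholds",
                call. = FALSE)
        return(AmplitudeThresholds(grid[1] - 1, grid[1], NA_real_))
    }
    nTotal <- lengths(amps)
    cnt <- .cumCountsAtGrid(amps, grid)        # samples x grid
    y <- labels == positive
    n1 <- sum(y); n0 <- sum(!y)
    pairs <- which(upper.tri(matrix(0, length(grid), length(grid))),
                   arr.ind = TRUE)             # (lower idx, upper idx)
    ## candidate order: smallest lower first, then largest upper, so the
    ## first optimum found realises the final tie rule
    pairs <- pairs[order(pairs[, 1], -pairs[, 2]), , drop = FALSE]
    nP <- nrow(pairs)
    auc <- numeric(nP); delta <- numeric(nP); negMed <- numeric(nP)
    for (r in seq_len(nP)) {
        frac <- (cnt[, pairs[r, 2]] - cnt[, pairs[r, 1]]) / nTotal
        auc[r] <- rocAuc(frac, y, positive = TRUE)
        ## class medians, not means: biological concentration spread is
        ## heavy-tailed, and a single outlier must not flip the separation
        delta[r] <- median(frac[y]) - median(frac[!y])
        negMed[r] <- median(frac[!y])
    }
    aMax <- max(auc)
    keep <- auc >= aMax - 3 * .hanleyMcNeilSE(aMax, n1, n0)
    score <- delta - backgroundPenalty * negMed
    best <- which(keep)[which.max(score[keep])]  # first max: tie rule
    AmplitudeThresholds(grid[pairs[best, 1]], grid[pairs[best, 2]],
                        auc[best])
}

#' Count positive droplets
#'
#' A droplet is positive iff its amplitude lies in `(lower, upper]`
#' (amplitudes exactly at the lower threshold are negative).
#'
#' @param amplitudes numeric amplitude vector of one well.
#' @param thresholds an [AmplitudeThresholds-class].
#' @return integer count.
#' @examples
#' countPositiveDroplets(c(1, 5, 9), AmplitudeThresholds(2, 6))  # 1
#' @export
countPositiveDroplets <- function(amplitudes, thresholds) {
    stopifnot(is(thresholds, "AmplitudeThresholds"))
    sum(amplitudes > thresholds@lower & amplitudes <= thresholds@upper)
}

#' Poisson absolute quantification of a digital PCR well
#'
#' Digital-PCR estimator: with `nPos` of `nTotal` droplets positive, the mean
#' copies per droplet is `lambda = -log(1 - nPos/nTotal)`; copies in the
#' partitioned reaction are `lambda * nTotal`, and scaling through elution /
#' template / plasma volumes gives copies per ml plasma. Saturated wells
#' (`nPos == nTotal`) are an error unless `continuityCorrection = TRUE`,
#' which substitutes `(nPos - 0.5)/nTotal`.
#'
#' @param nPos,nTotal positive and total droplet counts.
#' @param volumes volume chain, see [defaultVolumes()].
#' @param continuityCorrection allow saturated wells via the correction above.
#' @return list with `lambda`, `copiesPerReaction`, `copiesPerUlReaction`
#'   (via the droplet volume) and `concentration` (copies/ml plasma).
#' @examples
#' poissonConcentration(100, 10000)$lambda  # -log(0.99)
#' @export
poissonConcentration <- function(nPos, nTotal, volumes = defaultVolumes(),
                                 continuityCorrection = FALSE) {
    if (nTotal <= 0) stop("nTotal must be positive")
    if (nPos < 0 || nPos > nTotal) stop("nPos must lie in [0, nTotal]")
    if (nPos == nTotal) {
        if (!continuityCorrection)
            stop("saturated well (nPos == nTotal); ",
                 "set continuityCorrection = TRUE to quantify")
        nPos <- nPos - 0.5
    }
    lambda <- -log(1 - nPos / nTotal)
    copies <- lambda * nTotal
    list(lambda = lambda,
         copiesPerReaction = copies,
         copiesPerUlReaction = lambda / (volumes$dropletVolumeNl * 1e-3),
         concentration = copies *
             (volumes$elutionVolumeUl / volumes$reactionTemplateVolumeUl) /
             volumes$plasmaVolumeMl)
}

#' Determine a marker positivity cutoff
#'
#' Scans the midpoints between consecutive sorted unique concentrations and
#' returns the cutoff maximising the Youden index J = sensitivity +
#' specificity - 1 (positivity rule: concentration strictly above the
#' cutoff). Ties resolve to the lowest optimal cutoff. A cutoff with J = 0
#' (e.g. all concentrations identical) is flagged non-informative.
#'
#' @param concentrations per-sample copies/ml.
#' @param labels HV/BC labels aligned with `concentrations`.
#' @param positive the positive class label.
#' @return list with `cutoff`, `youdenJ` and `informative` (logical).
#' @export
determineMarkerCutoff <- function(concentrations, labels, positive = "BC") {
    labels <- as.character(labels)
    if (length(unique(labels)) < 2)
        stop("both classes are required to set a cutoff")
    y <- labels == positive
    u <- sort(unique(concentrations))
    cand <- if (length(u) == 1) u else (head(u, -1) + u[-1]) / 2
    nPos <- sum(y); nNeg <- sum(!y)
    J <- vapply(cand, function(ct) {
        sum(concentrations > ct & y) / nPos +
            sum(concentrations <= ct & !y) / nNeg - 1
    }, numeric(1))
    best <- which.max(J)  # first max = lowest cutoff on the sorted scan
    if (J[best] <= 0)
        warning("non-informative cutoff (Youden J <= 0)", call. = FALSE)
    list(cutoff = cand[best], youdenJ = J[best], informative = J[best] > 0)
}

#' Quantify all sample x marker reactions
#'
#' Pools all wells of each sample x marker, counts positive droplets at the
#' marker's thresholds, Poisson-corrects to copies/ml plasma and (when a
#' cutoff is available) calls positivity (`concentration > cutoff`).
#'
#' @param dropletData a [DropletData-class].
#' @param thresholds named list of [AmplitudeThresholds-class], one per
#'   marker.
#' @param cutoffs optional named numeric of copies/ml positivity cutoffs.
#' @param continuityCorrection passed to [poissonConcentration()].
#' @return data.frame (one row per sample x marker): `sample_id`, `marker`,
#'   `n_pos`, `n_total`, `lambda`, `concentration`, `log10_concentration`
#'   (of the raw concentration, -Inf at zero), `cutoff_used`, `positive_call`.
#' @export
quantifyMarkers <- function(dropletData, thresholds, cutoffs = NULL,
                            continuityCorrection = FALSE) {
    dt <- data.table::as.data.table(dropletTable(dropletData))
    vols <- dropletVolumes(dropletData)
    mks <- unique(dt$marker)
    missing <- setdiff(mks, names(thresholds))
    if (length(missing))
        stop("no thresholds for marker(s): ", paste(missing, collapse = ", "))
    lo <- vapply(thresholds, function(t) t@lower, numeric(1))
    hi <- vapply(thresholds, function(t) t@upper, numeric(1))
    amplitude <- marker <- sample_id <- NULL  # data.table NSE
    counts <- dt[, list(
        n_pos = sum(amplitude > lo[[marker[1]]] &
                    amplitude <= hi[[marker[1]]]),
        n_total = length(amplitude)),
        by = list(sample_id, marker)]
    counts <- as.data.frame(counts)
    q <- lapply(seq_len(nrow(counts)), function(i)
        poissonConcentration(counts$n_pos[i], counts$n_total[i], vols,
                             continuityCorrection))
    counts$lambda <- vapply(q, `[[`, numeric(1), "lambda")
    counts$concentration <- vapply(q, `[[`, numeric(1), "concentration")
    counts$log10_concentration <- log10(counts$concentration)
    counts$cutoff_used <- if (is.null(cutoffs)) NA_real_
                          else unname(cutoffs[counts$marker])
    counts$positive_call <- counts$concentration > counts$cutoff_used
    counts
}

#' Train the quantification state on labelled samples
#'
#' For every marker in the panel: optimise amplitude thresholds on the
#' training samples, quantify, and set the copies/ml positivity cutoff by the
#' Youden rule. The returned state is everything needed to process an
#' independent validation cohort with training-derived values only.
#'
#' @param dropletData training-cohort [DropletData-class].
#' @param labels named HV/BC vector (names = sample ids).
#' @param panel a [MarkerPanel()].
#' @param nGrid grid size for [optimizeAmplitudeThresholds()].
#' @param continuityCorrection quantify saturated wells (every droplet
#'   positive, as happens in template-overloaded internal-control reactions)
#'   with the `(nPos - 0.5)/nTotal` correction instead of failing; default
#'   `TRUE` at the pipeline level.
#' @return list with `thresholds` (named list of
#'   [AmplitudeThresholds-class]), `cutoffs` (named numeric), and `quants`
#'   (the training [quantifyMarkers()] table).
#' @export
trainQuantification <- function(dropletData, labels, panel = MarkerPanel(),
                                nGrid = 64, continuityCorrection = TRUE) {
    markers <- c(methylationMarkers(panel), internalControls(panel))
    thresholds <- lapply(setNames(markers, markers), function(m)
        optimizeAmplitudeThresholds(dropletData, m, labels, nGrid = nGrid))
    quants <- quantifyMarkers(dropletData, thresholds,
                              continuityCorrection = continuityCorrection)
    cutoffs <- vapply(setNames(markers, markers), function(m) {
        sub <- quants[quants$marker == m, ]
        determineMarkerCutoff(sub$concentration,
                              labels[sub$sample_id])$cutoff
    }, numeric(1))
    quants$cutoff_used <- unname(cutoffs[quants$marker])
    quants$positive_call <- quants$concentration > quants$cutoff_used
    list(thresholds = thresholds, cutoffs = cutoffs, quants = quants)
}
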