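## Synthetic cfDNA cohort: roster, per-sample true marker concentrations and
## droplet-level ddMSP amplitudes.
##
## The cohort model:
##   * total cfDNA concentration (copies/ml plasma) is log10-normal per class,
##     higher in BC than in healthy volunteers (HV) -- internal-control
##     markers read this concentration directly;
##   * each methylation marker carries a methylated fraction of the cfDNA that
##     rises with stage in BC and is near zero in HV; subtype-dominant markers
##     are only active in the matching subtype;
##   * each sample x marker reaction partitions the template into droplets:
##     the number of positive droplets is Poisson in (true copies per droplet
##     x droplet count), positive/negative amplitudes form two Gaussian
##     clusters, and a small "rain" fraction of droplets falls uniformly
##     between the cluster means.

.STAGES <- c("0", "I", "IIA", "IIB", "III", "IV")
.SUBTYPES <- c("luminal", "TN", "HER2", "luminal-HER2", "DCIS-unassessed")

#' Configuration for the synthetic cfDNA cohort
#'
#' Defaults encode the published study cohort: 133 HVs and 145 BC patients
#' with the published stage counts (0/I/IIA/IIB/III/IV = 4/47/31/22/9/32) and
#' subtype counts (luminal/TN/HER2/luminal-HER2/DCIS = 98/25/10/8/4), HV ages
#' uniform on 22-70 years and BC on 36-81 years, and 0.9 ml plasma per
#' sample. cfDNA levels (log10 copies/ml plasma: HV N(3.5, 0.25), BC
#' N(4.1, 0.30) -- healthy medians of ~3000 genome-equivalents/ml, elevated
#' several-fold in cancer) and the stage-dependent methylated fractions are
#' fixed so the assay's univariate structure holds: internal controls are
#' the strongest single features, single methylation markers sit in the
#' 0.55-0.75 AUC range, and the combined model separates classes with
#' training AUC well above 0.9.
#'
#' @param nHv,nBc class sizes.
#' @param stageDist named numeric over stages `0,I,IIA,IIB,III,IV`; counts or
#'   proportions (converted to counts by largest remainder).
#' @param subtypeDist named numeric over
#'   `luminal,TN,HER2,luminal-HER2,DCIS-unassessed`; counts or proportions.
#' @param ageRangeHv,ageRangeBc uniform age ranges in years.
#' @param cfdnaLog10MeanHv,cfdnaLog10SdHv,cfdnaLog10MeanBc,cfdnaLog10SdBc
#'   per-class log10 cfDNA concentration (copies/ml plasma) parameters.
#' @param hvMethFraction methylated fraction of cfDNA at a marker locus in
#'   samples without that signal (HVs, and non-matching subtypes for
#'   subtype-dominant markers).
#' @param stageMethFraction named numeric, methylated fraction per stage for
#'   an active marker.
#' @param methFractionLogSd dex-scale lognormal noise on per-sample marker
#'   fractions.
#' @param icLogSd dex-scale noise of internal-control reactions around the
#'   sample's true cfDNA concentration.
#' @param nDroplets droplets generated per well.
#' @param negMean,negSd,posMean,posSd amplitude cluster parameters
#'   (`posMean > negMean` required).
#' @param rainFraction fraction of negative droplets re-drawn uniformly
#'   between the cluster means ("rain").
#' @param plasmaVolumeMl plasma input per sample.
#' @param dcisStagePairing force DCIS-unassessed subtype onto stage-0 samples
#'   (as in the published cohort table).
#' @param seed integer RNG seed.
#' @return A validated list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nHv = 133, nBc = 145,
                            stageDist = c("0" = 4, I = 47, IIA = 31,
                                          IIB = 22, III = 9, IV = 32),
                            subtypeDist = c(luminal = 98, TN = 25, HER2 = 10,
                                            "luminal-HER2" = 8,
                                            "DCIS-unassessed" = 4),
                            ageRangeHv = c(22, 70), ageRangeBc = c(36, 81),
                            cfdnaLog10MeanHv = 3.50, cfdnaLog10SdHv = 0.25,
                            cfdnaLog10MeanBc = 4.10, cfdnaLog10SdBc = 0.30,
                            hvMethFraction = 0.02,
                            stageMethFraction = c("0" = 0.024, I = 0.027,
                                                  IIA = 0.033, IIB = 0.041,
                                                  III = 0.052, IV = 0.068),
                            methFractionLogSd = 0.8,
                            icLogSd = 0.05,
                            nDroplets = 12000,
                            negMean = 1000, negSd = 100,
                            posMean = 8000, posSd = 300,
                            rainFraction = 0.001,
                            plasmaVolumeMl = 0.9,
                            dcisStagePairing = TRUE,
                            seed = 1L) {
    cfg <- as.list(environment())
    if (!setequal(names(cfg$stageDist), .STAGES))
        stop("stageDist must name stages ", paste(.STAGES, collapse = ", "))
    if (!setequal(names(cfg$subtypeDist), .SUBTYPES))
        stop("subtypeDist must name subtypes ",
             paste(.SUBTYPES, collapse = ", "))
    if (any(cfg$stageDist < 0) || any(cfg$subtypeDist < 0))
        stop("distributions must be non-negative")
    if (posMean <= negMean) stop("posMean must exceed negMean")
    if (nDroplets <= 0) stop("nDroplets must be positive")
    if (rainFraction < 0 || rainFraction > 1)
        stop("rainFraction must lie in [0, 1]")
    cfg$seed <- as.integer(seed)
    class(cfg) <- "CohortSimConfig"
    cfg
}

#' Named cohort presets
#'
#' `"table1_cohort"` is the published 278-sample cohort composition (the
#' [cohortSimConfig()] defaults). `"toy"` is a desk-scale cohort (30 HV /
#' 30 BC, 4000 droplets per well) with the same effect-size structure, used
#' throughout the test-suite examples.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned config.
#' @return A `CohortSimConfig`.
#' @export
cohortPreset <- function(name = c("table1_cohort", "toy"), seed = 1L) {
    name <- match.arg(name)
    switch(name,
           table1_cohort = cohortSimConfig(seed = seed),
           toy = cohortSimConfig(
               nHv = 30, nBc = 30,
               stageDist = c("0" = 1, I = 10, IIA = 6, IIB = 5,
                             III = 2, IV = 6),
               subtypeDist = c(luminal = 20, TN = 5, HER2 = 2,
                               "luminal-HER2" = 2, "DCIS-unassessed" = 1),
               nDroplets = 4000, seed = seed))
}

## largest-remainder conversion of proportions/counts to exact counts
.apportion <- function(dist, n) {
    if (sum(dist) == 0) stop("distribution has no mass")
    target <- dist / sum(dist) * n
    base <- floor(target)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' Simulate a sample roster
#'
#' One record per sample: class (HV/BC), stage (`"none"` for HVs), subtype,
#' age and plasma volume. Stage and subtype counts follow the configured
#' distributions exactly (largest-remainder apportionment for proportions);
#' when `dcisStagePairing` is set, DCIS-unassessed subtypes are placed on
#' stage-0 samples first.
#'
#' @param cfg a [cohortSimConfig()] configuration.
#' @return data.frame with columns `sample_id`, `class`, `stage`, `subtype`,
#'   `age`, `plasma_volume_ml`, `split` (initially `"unassigned"`).
#' @examples
#' nrow(simulateRoster(cohortPreset("table1_cohort")))  # 278
#' @export
simulateRoster <- function(cfg = cohortPreset("table1_cohort")) {
    stopifnot(inherits(cfg, "CohortSimConfig"))
    set.seed(cfg$seed)
    n <- cfg$nHv + cfg$nBc
    stageCounts <- .apportion(cfg$stageDist[.STAGES], cfg$nBc)
    subtypeCounts <- .apportion(cfg$subtypeDist[.SUBTYPES], cfg$nBc)
    stages <- rep(.STAGES, stageCounts)
    subtypes <- rep(.SUBTYPES, subtypeCounts)
    resample <- function(x) x[sample.int(length(x))]
    ## pair subtypes to stages: optionally pin DCIS to stage 0, shuffle rest
    if (cfg$nBc > 0) stages <- resample(stages)
    if (cfg$dcisStagePairing && cfg$nBc > 0) {
        dcis <- subtypes == "DCIS-unassessed"
        st0 <- which(stages == "0")
        nPin <- min(sum(dcis), length(st0))
        rest <- resample(subtypes[!dcis | cumsum(dcis) > nPin])
        out <- character(cfg$nBc)
        out[head(st0, nPin)] <- "DCIS-unassessed"
        out[out == ""] <- rest
        subtypes <- out
    } else if (cfg$nBc > 0) {
        subtypes <- resample(subtypes)
    }
    age <- c(round(runif(cfg$nHv, cfg$ageRangeHv[1], cfg$ageRangeHv[2])),
             round(runif(cfg$nBc, cfg$ageRangeBc[1], cfg$ageRangeBc[2])))
    data.frame(
        sample_id = sprintf("S%04d", seq_len(n)),
        class = rep(c("HV", "BC"), c(cfg$nHv, cfg$nBc)),
        stage = c(rep("none", cfg$nHv), stages),
        subtype = c(rep("none", cfg$nHv), subtypes),
        age = age,
        plasma_volume_ml = cfg$plasmaVolumeMl,
        split = "unassigned",
        stringsAsFactors = FALSE)
}

## Expected true copies loaded into one reaction, given copies/ml plasma.
## Inverse of the quantification volume chain: plasma -> elution -> template.
.copiesPerReaction <- function(concentration, volumes) {
    concentration * volumes$plasmaVolumeMl *
        volumes$reactionTemplateVolumeUl / volumes$elutionVolumeUl
}

## panel order defines marker class: first third common, then
## luminal-dominant, then TN-dominant (4+4+4 for the published panel)
.markerClass <- function(panel) {
    mm <- methylationMarkers(panel)
    third <- ceiling(length(mm) / 3)
    n2 <- min(length(mm) - third, third)
    cls <- rep(c("common", "luminal", "TN"),
               c(third, n2, max(0, length(mm) - third - n2)))
    setNames(cls, mm)
}

#' Simulate droplet-level ddMSP data for a cohort
#'
#' For every sample x marker reaction, the true methylated-fragment
#' concentration is drawn from the cohort model, converted to expected copies
#' per reaction, and realised as a droplet amplitude list: positive-droplet
#' count ~ Poisson(copies), with two-cluster Gaussian amplitudes and a
#' configurable rain fraction between the clusters. Ground truth (true
#' concentration, copies per reaction, positive count drawn) is returned as a
#' manifest.
#'
#' The 12 methylation markers are treated as 4 common + 4 luminal-dominant +
#' 4 TN-dominant (panel order); subtype-dominant markers are active in the
#' matching subtype only (luminal-HER2 counts as luminal), all markers are
#' active in common for BC, and inactive markers sit at the HV background
#' fraction. Internal controls read the sample's total cfDNA concentration.
#'
#' @param roster a roster from [simulateRoster()].
#' @param panel a [MarkerPanel()].
#' @param cfg the [cohortSimConfig()] used for the roster.
#' @param volumes volume chain, see [defaultVolumes()]; `plasmaVolumeMl` is
#'   taken from `cfg`.
#' @return list with `droplets` (a [DropletData-class]) and `manifest`
#'   (data.frame: `sample_id`, `marker`, `true_concentration`,
#'   `true_copies_per_reaction`, `lambda`, `n_positive_drawn`).
#' @export
simulateDroplets <- function(roster, panel = MarkerPanel(),
                             cfg = cohortPreset("table1_cohort"),
                             volumes = defaultVolumes()) {
    stopifnot(inherits(cfg, "CohortSimConfig"), nrow(roster) > 0)
    volumes$plasmaVolumeMl <- cfg$plasmaVolumeMl
    set.seed(cfg$seed + 1L)  # distinct stream from the roster draw
    nS <- nrow(roster)
    isBC <- roster$class == "BC"
    cfdna <- 10^rnorm(nS,
                      ifelse(isBC, cfg$cfdnaLog10MeanBc, cfg$cfdnaLog10MeanHv),
                      ifelse(isBC, cfg$cfdnaLog10SdBc, cfg$cfdnaLog10SdHv))

    mkClass <- .markerClass(panel)
    allMarkers <- c(methylationMarkers(panel), internalControls(panel))
    chan <- panel@channelMap

    manifest <- vector("list", length(allMarkers))
    chunks <- vector("list", length(allMarkers) * nS)
    k <- 0L
    for (m in allMarkers) {
        if (m %in% internalControls(panel)) {
            conc <- cfdna * 10^rnorm(nS, 0, cfg$icLogSd)
        } else {
            active <- isBC & (mkClass[m] == "common" |
                (mkClass[m] == "luminal" &
                     roster$subtype %in% c("luminal", "luminal-HER2")) |
                (mkClass[m] == "TN" & roster$subtype == "TN"))
            frac <- ifelse(active,
                           cfg$stageMethFraction[roster$stage],
                           cfg$hvMethFraction)
            frac[is.na(frac)] <- cfg$hvMethFraction
            conc <- cfdna * frac * 10^rnorm(nS, 0, cfg$methFractionLogSd)
        }
        copies <- .copiesPerReaction(conc, volumes)
        lambda <- copies / cfg$nDroplets
        ## Poisson partitioning: a droplet is positive iff it received >= 1
        ## of the reaction's copies, so the positive count is Binomial in
        ## the zero-truncation probability 1 - exp(-lambda)
        nPos <- rbinom(nS, cfg$nDroplets, 1 - exp(-lambda))
        manifest[[match(m, allMarkers)]] <- data.frame(
            sample_id = roster$sample_id, marker = m,
            true_concentration = conc,
            true_copies_per_reaction = copies,
            lambda = lambda, n_positive_drawn = nPos,
            stringsAsFactors = FALSE)
        ## vectorised amplitude draw over all wells of this marker: within a
        ## well the first nPos droplets are positive, then rain, then negative
        nNeg <- cfg$nDroplets - nPos
        nRain <- rbinom(nS, nNeg, cfg$rainFraction)
        within <- sequence(rep.int(cfg$nDroplets, nS))
        npR <- rep.int(nPos, rep.int(cfg$nDroplets, nS))
        nrR <- rep.int(nPos + nRain, rep.int(cfg$nDroplets, nS))
        typ <- 1L + (within > npR) + (within > nrR)  # 1 pos, 2 rain, 3 neg
        amp <- numeric(length(typ))
        amp[typ == 1L] <- rnorm(sum(typ == 1L), cfg$posMean, cfg$posSd)
        amp[typ == 2L] <- runif(sum(typ == 2L), cfg$negMean, cfg$posMean)
        amp[typ == 3L] <- rnorm(sum(typ == 3L), cfg$negMean, cfg$negSd)
        amp <- pmax(amp, 1)  # readers report positive amplitudes
        k <- k + 1L
        chunks[[k]] <- data.table::data.table(
            sample_id = rep.int(roster$sample_id,
                                rep.int(cfg$nDroplets, nS)),
            marker = m, well = "A01", channel = unname(chan[m]),
            amplitude = amp)
    }
    droplets <- data.table::rbindlist(chunks[seq_len(k)])
    list(droplets = DropletData(droplets, volumes),
         manifest = do.call(rbind, manifest))
}
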