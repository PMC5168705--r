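## Synthetic beta-value array data with planted marker structure.
##
## The generator emulates a discovery panel: breast-cancer (BC) samples of
## luminal and triple-negative (TN) subtype, each profiled from cell lines and
## from FFPE tissue, plus non-cancer blood and epithelia samples, on a
## low-methylation background (beta << 0.05 in non-cancer). Four classes of
## probes are planted, one per downstream selection condition:
##   common-a : strongly methylated in all BC (widest BC-NC gap)
##   common-b : moderately methylated in all BC, near-zero in non-cancer
##              (lowest meanNC among probes with meanBC > 0.6)
##   luminal-dominant / TN-dominant : methylated in one subtype only.

#' Configuration for the synthetic beta-value array
#'
#' Sample-stratum sizes default to a realistic discovery panel (7 luminal
#' cell lines, 42 luminal FFPE, 18 TN cell lines, 11 TN FFPE, 29 blood,
#' 2 normal epithelia). Planted effect means are fixed so that each probe
#' class wins exactly one of the four selection conditions: common-a probes
#' have beta ~0.95 in every BC stratum; common-b probes have beta ~0.7 in BC
#' but an ultra-low non-cancer background (mean 0.001 vs 0.02 elsewhere);
#' subtype-dominant probes are ~0.9 in their subtype and background in the
#' other.
#'
#' @param nProbes total probes on the simulated array.
#' @param nSamples named integer vector of stratum sizes (names
#'   `lumCellLine`, `lumFFPE`, `tnCellLine`, `tnFFPE`, `ncBlood`,
#'   `ncEpithelia`).
#' @param nPlanted named integer vector of planted probe counts (names
#'   `commonA`, `commonB`, `luminalDominant`, `tnDominant`).
#' @param backgroundBetaMean,backgroundBetaSd background (unmethylated) beta
#'   distribution; the mean must stay below 0.05 so non-planted probes pass
#'   no selection condition.
#' @param commonBNcMean,commonBNcSd the ultra-low non-cancer background of
#'   common-b probes.
#' @param plantedBetaSd sampling sd of planted (methylated) betas.
#' @param betaHigh,betaMid methylated beta levels for the strong (common-a,
#'   subtype-dominant) and moderate (common-b) planted classes.
#' @param seed integer RNG seed; all draws are deterministic given it.
#' @return A validated list of class `ArraySimConfig`.
#' @export
arraySimConfig <- function(nProbes = 20000,
                           nSamples = c(lumCellLine = 7, lumFFPE = 42,
                                        tnCellLine = 18, tnFFPE = 11,
                                        ncBlood = 29, ncEpithelia = 2),
                           nPlanted = c(commonA = 20, commonB = 20,
                                        luminalDominant = 50, tnDominant = 50),
                           backgroundBetaMean = 0.02, backgroundBetaSd = 0.012,
                           commonBNcMean = 0.001, commonBNcSd = 0.0005,
                           plantedBetaSd = 0.03,
                           betaHigh = 0.95, betaMid = 0.70,
                           seed = 1L) {
    cfg <- list(nProbes = as.integer(nProbes),
                nSamples = nSamples, nPlanted = nPlanted,
                backgroundBetaMean = backgroundBetaMean,
                backgroundBetaSd = backgroundBetaSd,
                commonBNcMean = commonBNcMean, commonBNcSd = commonBNcSd,
                plantedBetaSd = plantedBetaSd,
                betaHigh = betaHigh, betaMid = betaMid,
                seed = as.integer(seed))
    needS <- c("lumCellLine", "lumFFPE", "tnCellLine", "tnFFPE",
               "ncBlood", "ncEpithelia")
    needP <- c("commonA", "commonB", "luminalDominant", "tnDominant")
    if (!all(needS %in% names(cfg$nSamples)))
        stop("nSamples must name strata: ", paste(needS, collapse = ", "))
    if (!all(needP %in% names(cfg$nPlanted)))
        stop("nPlanted must name classes: ", paste(needP, collapse = ", "))
    if (sum(cfg$nPlanted) > cfg$nProbes)
        stop("planted probe counts exceed nProbes")
    if (backgroundBetaMean >= 0.05)
        stop("backgroundBetaMean must be < 0.05")
    class(cfg) <- "ArraySimConfig"
    cfg
}

.clip01 <- function(x) {  # dim-preserving clip to [0, 1]
    x[x < 0] <- 0
    x[x > 1] <- 1
    x
}

#' Simulate a beta-value array with planted candidate markers
#'
#' Draws a probes x samples beta matrix under `cfg` and records every planted
#' probe in a ground-truth manifest, so downstream marker selection can be
#' scored for recall and precision.
#'
#' @param cfg an [arraySimConfig()] configuration.
#' @return A list with elements `experiment` (a
#'   [BetaArrayExperiment-class]) and `manifest` (data.frame with columns
#'   `probe_id`, `class` in
#'   `commonA`/`commonB`/`luminalDominant`/`tnDominant`).
#' @examples
#' sim <- simulateArrayData(arraySimConfig(nProbes = 2000, seed = 7))
#' table(sim$manifest$class)
#' @export
simulateArrayData <- function(cfg = arraySimConfig()) {
    stopifnot(inherits(cfg, "ArraySimConfig"))
    set.seed(cfg$seed)
    ns <- cfg$nSamples
    groups <- c(rep("BC-luminal", ns["lumCellLine"] + ns["lumFFPE"]),
                rep("BC-TN", ns["tnCellLine"] + ns["tnFFPE"]),
                rep("non-BC", ns["ncBlood"] + ns["ncEpithelia"]))
    materials <- c(rep("cell-line", ns["lumCellLine"]),
                   rep("FFPE", ns["lumFFPE"]),
                   rep("cell-line", ns["tnCellLine"]),
                   rep("FFPE", ns["tnFFPE"]),
                   rep("blood", ns["ncBlood"]),
                   rep("epithelia", ns["ncEpithelia"]))
    nSamp <- length(groups)
    probe_ids <- sprintf("cg%07d", seq_len(cfg$nProbes))

    ## background everywhere, then overwrite planted blocks
    beta <- matrix(rnorm(cfg$nProbes * nSamp, cfg$backgroundBetaMean,
                         cfg$backgroundBetaSd),
                   nrow = cfg$nProbes,
                   dimnames = list(probe_ids, sprintf("arr%03d", seq_len(nSamp))))

    np <- cfg$nPlanted
    idx <- split(seq_len(sum(np)),
                 rep(names(np), np))[names(np)[np > 0]]
    isBC <- groups != "non-BC"
    isLum <- groups == "BC-luminal"
    isTN <- groups == "BC-TN"
    isNC <- !isBC
    fill <- function(rows, cols, mean, sd = cfg$plantedBetaSd) {
        beta[rows, cols] <<- rnorm(length(rows) * sum(cols), mean, sd)
    }
    if (!is.null(idx$commonA))
        fill(idx$commonA, isBC, cfg$betaHigh)
    if (!is.null(idx$commonB)) {
        fill(idx$commonB, isBC, cfg$betaMid)
        fill(idx$commonB, isNC, cfg$commonBNcMean, cfg$commonBNcSd)
    }
    if (!is.null(idx$luminalDominant))
        fill(idx$luminalDominant, isLum, cfg$betaHigh)
    if (!is.null(idx$tnDominant))
        fill(idx$tnDominant, isTN, cfg$betaHigh)
    beta <- .clip01(beta)

    manifest <- data.frame(
        probe_id = probe_ids[unlist(idx, use.names = FALSE)],
        class = rep(names(idx), lengths(idx)),
        stringsAsFactors = FALSE)
    list(experiment = BetaArrayExperiment(beta, groups, materials),
         manifest = manifest)
}
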