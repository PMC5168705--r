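## Candidate marker selection from beta-value arrays.
##
## Group means: because the luminal and TN groups contain very different
## proportions of cell-line and FFPE samples, a pooled mean would be biased
## toward whichever material dominates. The BC-side means are therefore
## balanced: the unweighted average of the cell-line-stratum mean and the
## FFPE-stratum mean. The non-cancer mean (meanNC) is a plain mean over all
## non-BC samples (blood, epithelia, non-BC cell lines) -- a cfDNA marker
## must be unmethylated in blood above all.

#' Candidate marker set
#'
#' @slot table data.frame, one row per probe x condition, with the selection
#'   criterion value, rank, group means and Welch test statistics (NA when no
#'   experiment was supplied).
#' @slot uniqueLoci character, deduplicated probe identifiers across the four
#'   conditions.
#' @slot shortfall named integer, per condition, how many requested slots
#'   could not be filled from the eligible pool.
#' @exportClass CandidateSet
setClass("CandidateSet",
         representation(table = "data.frame", uniqueLoci = "character",
                        shortfall = "integer"))

#' @export
setMethod("show", "CandidateSet", function(object) {
    tab <- table(object@table$condition)
    cat("CandidateSet:", length(object@uniqueLoci), "unique loci (",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), ")\n")
    if (any(object@shortfall > 0))
        cat("  shortfall:",
            paste(sprintf("%s:%d", names(object@shortfall),
                          object@shortfall)[object@shortfall > 0],
                  collapse = " "), "\n")
})

#' @describeIn CandidateSet-class per-condition candidate table.
#' @param x a `CandidateSet`.
#' @export
candidateTable <- function(x) x@table

#' @describeIn CandidateSet-class deduplicated selected loci.
#' @export
uniqueLoci <- function(x) x@uniqueLoci

#' @describeIn CandidateSet-class unfilled slots per condition.
#' @export
selectionShortfall <- function(x) x@shortfall

.strataMean <- function(beta, cols, materials, probe_names) {
    ## balanced mean: average of the cell-line-stratum mean and the
    ## FFPE-stratum mean; falls back to the available stratum with a warning
    cl <- cols & materials == "cell-line"
    ff <- cols & materials == "FFPE"
    rmean <- function(sel) rowMeans(beta[, sel, drop = FALSE])
    if (any(cl) && any(ff)) (rmean(cl) + rmean(ff)) / 2
    else if (any(cl) || any(ff)) {
        warning("group has a single material stratum; ",
                "using its plain mean", call. = FALSE)
        rmean(cl | ff)
    } else stop("group has no samples in any stratum")
}

#' Compute per-probe group mean beta values
#'
#' Returns the four per-probe means candidate selection operates on: `meanNC`
#' (plain mean over non-BC samples), and `meanBC`, `meanLum`, `meanTN`
#' (balanced cell-line/FFPE means over all BC, luminal BC and TN BC samples
#' respectively). `meanBC` can be switched to a pooled (unbalanced) mean.
#'
#' @param experiment a [BetaArrayExperiment-class].
#' @param bcMean `"balanced"` (default) averages the BC cell-line-stratum and
#'   FFPE-stratum means; `"pooled"` is the plain mean over all BC samples.
#' @return data.frame with columns `probe_id`, `meanNC`, `meanBC`, `meanLum`,
#'   `meanTN`.
#' @examples
#' sim <- simulateArrayData(arraySimConfig(nProbes = 500))
#' head(computeGroupMeans(sim$experiment))
#' @export
computeGroupMeans <- function(experiment, bcMean = c("balanced", "pooled")) {
    stopifnot(is(experiment, "BetaArrayExperiment"))
    bcMean <- match.arg(bcMean)
    beta <- SummarizedExperiment::assay(experiment, "beta")
    grp <- experiment$group
    mat <- experiment$material
    isBC <- grp != "non-BC"
    if (!any(isBC) || all(isBC))
        stop("both BC and non-BC samples are required")
    meanNC <- rowMeans(beta[, !isBC, drop = FALSE])
    meanBC <- if (bcMean == "balanced")
        .strataMean(beta, isBC, mat, rownames(beta))
    else rowMeans(beta[, isBC, drop = FALSE])
    meanLum <- .strataMean(beta, grp == "BC-luminal", mat, rownames(beta))
    meanTN <- .strataMean(beta, grp == "BC-TN", mat, rownames(beta))
    data.frame(probe_id = rownames(beta), meanNC = meanNC, meanBC = meanBC,
               meanLum = meanLum, meanTN = meanTN,
               row.names = NULL, stringsAsFactors = FALSE)
}

## deterministic top-k: by criterion (descending unless ascending=TRUE),
## ties broken by lexicographic probe_id
.topK <- function(df, value, k, ascending = FALSE) {
    if (nrow(df) == 0 || k == 0) {
        out <- df[integer(0), , drop = FALSE]
        out$criterion_value <- numeric(0)
        return(out)
    }
    o <- if (ascending) order(value, df$probe_id)
         else order(-value, df$probe_id)
    df <- df[o, , drop = FALSE]
    df$criterion_value <- value[o]
    head(df, k)
}

#' Select candidate markers by the four top-k conditions
#'
#' Operating on probes with `meanNC < ncCeiling` (eligible pool), selects:
#' (a) the top `kA` loci by the gap `meanBC - meanNC` (common markers);
#' (b) the top `kB` loci of lowest `meanNC` among probes with
#' `meanBC > betaBcFloor` (common markers); (c) the top `kC` loci by
#' `meanLum - meanTN` (luminal-dominant); (d) the top `kD` loci by
#' `meanTN - meanLum` (TN-dominant). Conditions are evaluated independently;
#' a probe can appear under several conditions but is counted once in
#' `uniqueLoci`. Ties are broken by lexicographic probe identifier. If an
#' eligible pool cannot fill a condition, all eligible probes are returned
#' and the shortfall recorded.
#'
#' When `experiment` is supplied, each selected probe is annotated with the
#' Welch unequal-variance t statistic and two-sided p value comparing its BC
#' and non-BC beta values.
#'
#' @param means output of [computeGroupMeans()].
#' @param kA,kB,kC,kD per-condition top-k sizes (defaults 20/20/50/50).
#' @param betaBcFloor minimum `meanBC` for condition (b).
#' @param ncCeiling eligibility ceiling on `meanNC`.
#' @param experiment optional [BetaArrayExperiment-class] for Welch tests.
#' @return A [CandidateSet-class].
#' @examples
#' sim <- simulateArrayData(arraySimConfig(nProbes = 2000))
#' cs <- selectCandidates(computeGroupMeans(sim$experiment),
#'                        experiment = sim$experiment)
#' length(uniqueLoci(cs))  # 140
#' @export
selectCandidates <- function(means, kA = 20, kB = 20, kC = 50, kD = 50,
                             betaBcFloor = 0.6, ncCeiling = 0.05,
                             experiment = NULL) {
    elig <- means[means$meanNC < ncCeiling, , drop = FALSE]
    condA <- .topK(elig, elig$meanBC - elig$meanNC, kA)
    poolB <- elig[elig$meanBC > betaBcFloor, , drop = FALSE]
    condB <- .topK(poolB, poolB$meanNC, kB, ascending = TRUE)
    condC <- .topK(elig, elig$meanLum - elig$meanTN, kC)
    condD <- .topK(elig, elig$meanTN - elig$meanLum, kD)
    parts <- list(a = condA, b = condB, c = condC, d = condD)
    ks <- c(a = kA, b = kB, c = kC, d = kD)
    shortfall <- vapply(names(parts),
                        function(nm) as.integer(ks[nm] - nrow(parts[[nm]])),
                        integer(1))
    if (any(shortfall > 0))
        warning("eligible pool could not fill condition(s): ",
                paste(names(shortfall)[shortfall > 0], collapse = ", "),
                call. = FALSE)
    for (nm in names(parts)) {
        p <- parts[[nm]]
        p$condition <- rep(nm, nrow(p))
        p$rank <- seq_len(nrow(p))
        parts[[nm]] <- p
    }
    tab <- do.call(rbind, parts)
    rownames(tab) <- NULL
    if (nrow(tab) == 0)
        tab <- data.frame(probe_id = character(), meanNC = numeric(),
                          meanBC = numeric(), meanLum = numeric(),
                          meanTN = numeric(), criterion_value = numeric(),
                          condition = character(), rank = integer())
    tab$welch_t <- rep(NA_real_, nrow(tab))
    tab$welch_p <- rep(NA_real_, nrow(tab))
    if (!is.null(experiment) && nrow(tab) > 0) {
        beta <- SummarizedExperiment::assay(experiment, "beta")
        isBC <- experiment$group != "non-BC"
        for (pid in unique(tab$probe_id)) {
            wt <- tryCatch(welchTest(beta[pid, isBC], beta[pid, !isBC]),
                           error = function(e) list(t = NA_real_,
                                                    p = NA_real_))
            tab$welch_t[tab$probe_id == pid] <- wt$t
            tab$welch_p[tab$probe_id == pid] <- wt$p
        }
    }
    new("CandidateSet", table = tab,
        uniqueLoci = sort(unique(tab$probe_id)), shortfall = shortfall)
}

#' Welch unequal-variance t test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`
#' (Welch-Satterthwaite degrees of freedom), returning the statistic and the
#' two-sided p value. Degenerate input (fewer than two values per group, or
#' zero variance in both groups) is an error.
#'
#' @param x,y numeric vectors for the two groups.
#' @return list with elements `t` and `p`.
#' @examples
#' welchTest(c(1, 2, 3), c(11, 12, 13))
#' @export
welchTest <- function(x, y) {
    if (length(x) < 2 || length(y) < 2)
        stop("both groups need at least two values")
    if (sd(x) == 0 && sd(y) == 0) {
        if (mean(x) == mean(y)) return(list(t = 0, p = 1))
        stop("degenerate variance: both groups are constant")
    }
    ht <- t.test(x, y, var.equal = FALSE)
    list(t = unname(ht$statistic), p = ht$p.value)
}
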