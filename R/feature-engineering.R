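## The 15-variable per-sample feature table:
##   m1..m12 : log10(marker concentration + epsilon), copies/ml plasma
##   Mean12  : arithmetic mean of m1..m12 (log scale; linear available)
##   IC      : log10 geometric mean of the four internal-control
##             concentrations (each floored at epsilon), i.e. the arithmetic
##             mean of their log10 values -- the assay's cfDNA concentration
##   Npos    : number of methylation-positive markers (of 12)

#' Default epsilon for log10 conversion
#'
#' The copies/ml-plasma equivalent of half a copy per reaction under the
#' given volume chain; added to methylation-marker concentrations (and used
#' as the internal-control floor) before taking log10, so zero-positive
#' wells stay finite.
#'
#' @param volumes volume chain, see [defaultVolumes()].
#' @return numeric scalar (about 5.56 copies/ml at default volumes).
#' @export
defaultEpsilon <- function(volumes = defaultVolumes()) {
    0.5 * (volumes$elutionVolumeUl / volumes$reactionTemplateVolumeUl) /
        volumes$plasmaVolumeMl
}

#' Count methylation-positive markers
#'
#' @param calls logical vector of exactly 12 per-marker positivity calls.
#' @return integer in 0..12.
#' @export
countPositiveMarkers <- function(calls) {
    if (length(calls) != 12 || anyNA(calls) || !is.logical(calls))
        stop("exactly 12 non-missing logical calls are required")
    sum(calls)
}

#' Build the 15-variable feature table
#'
#' Assembles, per sample, the 12 methylation-marker log10 concentrations,
#' their mean (`Mean12`), the log10 geometric-mean internal-control
#' concentration (`IC`) and the positive-marker count (`Npos`) from a
#' [quantifyMarkers()] table. Samples missing any of the 16 panel markers
#' are dropped with a message.
#'
#' @param quants a [quantifyMarkers()] table with positivity calls.
#' @param panel a [MarkerPanel()].
#' @param epsilon copies/ml added to marker concentrations (and flooring the
#'   internal controls) before log10; default [defaultEpsilon()].
#' @param mean12Scale `"log"` (default) averages the log10 values;
#'   `"linear"` takes log10 of the mean concentration.
#' @return data.frame: `sample_id` plus 15 numeric columns (the 12 marker
#'   names, `Mean12`, `IC`, `Npos`).
#' @export
buildFeatureTable <- function(quants, panel = MarkerPanel(),
                              epsilon = defaultEpsilon(),
                              mean12Scale = c("log", "linear")) {
    mean12Scale <- match.arg(mean12Scale)
    mm <- methylationMarkers(panel)
    ic <- internalControls(panel)
    stopifnot(length(mm) == 12, length(ic) == 4)
    samples <- unique(quants$sample_id)
    rows <- vector("list", length(samples))
    dropped <- character()
    for (i in seq_along(samples)) {
        s <- samples[i]
        sub <- quants[quants$sample_id == s, ]
        if (!all(c(mm, ic) %in% sub$marker)) {
            dropped <- c(dropped, s)
            next
        }
        conc <- setNames(sub$concentration, sub$marker)
        calls <- setNames(sub$positive_call, sub$marker)
        m <- log10(conc[mm] + epsilon)
        mean12 <- if (mean12Scale == "log") mean(m)
                  else log10(mean(conc[mm] + epsilon))
        icv <- mean(log10(pmax(conc[ic], epsilon)))  # log10 geometric mean
        rows[[i]] <- data.frame(
            sample_id = s, as.list(setNames(as.numeric(m), mm)),
            Mean12 = mean12, IC = icv,
            Npos = countPositiveMarkers(unname(calls[mm])),
            check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (length(dropped))
        message("dropped ", length(dropped),
                " sample(s) with missing marker reactions: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else "")
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) stop("no sample had a complete marker panel")
    rownames(out) <- NULL
    out
}

#' Names of the 15 model variables
#'
#' @param panel a [MarkerPanel()].
#' @return character vector: the 12 methylation markers, `Mean12`, `IC`,
#'   `Npos`.
#' @export
featureVariableNames <- function(panel = MarkerPanel()) {
    c(methylationMarkers(panel), "Mean12", "IC", "Npos")
}
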