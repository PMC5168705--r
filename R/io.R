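## Plain-text readers/writers for the pipeline's interchange formats:
## beta-matrix TSV + sample-sheet CSV, roster CSV, long droplet CSV, and the
## model-state JSON that carries training-derived thresholds, cutoffs and
## the selected model into validation scoring.

#' Write / read a beta-value matrix with its sample sheet
#'
#' The matrix is a TSV with probes in rows (first column `probe_id`) and one
#' column per sample; the sample sheet is a CSV with columns `sample_id`,
#' `group`, `material`.
#'
#' @param experiment a [BetaArrayExperiment-class].
#' @param betaFile,sampleSheetFile output/input paths.
#' @return `writeBetaMatrix` returns the paths invisibly; `readBetaMatrix`
#'   returns a [BetaArrayExperiment-class].
#' @export
writeBetaMatrix <- function(experiment, betaFile, sampleSheetFile) {
    beta <- SummarizedExperiment::assay(experiment, "beta")
    dt <- data.table::data.table(probe_id = rownames(beta), beta)
    data.table::fwrite(dt, betaFile, sep = "\t")
    data.table::fwrite(
        data.frame(sample_id = colnames(beta),
                   group = experiment$group,
                   material = experiment$material),
        sampleSheetFile)
    invisible(c(betaFile, sampleSheetFile))
}

#' @rdname writeBetaMatrix
#' @export
readBetaMatrix <- function(betaFile, sampleSheetFile) {
    dt <- data.table::fread(betaFile, sep = "\t")
    beta <- as.matrix(dt[, -1])
    rownames(beta) <- dt[[1]]
    sheet <- data.table::fread(sampleSheetFile)
    sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
    BetaArrayExperiment(beta, sheet$group, sheet$material)
}

#' Write / read a sample roster CSV
#'
#' @param roster roster data.frame (see [simulateRoster()]).
#' @param file path.
#' @export
writeRoster <- function(roster, file) {
    data.table::fwrite(roster, file)
    invisible(file)
}

#' @rdname writeRoster
#' @export
readRoster <- function(file) {
    as.data.frame(data.table::fread(file,
                                    colClasses = list(character = "stage")))
}

#' Write / read droplet data CSV
#'
#' Long format, one droplet per row: `sample_id`, `marker`, `well`,
#' `channel`, `amplitude`. Volumes are not stored in the CSV; supply them on
#' read.
#'
#' @param dropletData a [DropletData-class].
#' @param file path.
#' @param volumes volume chain used on read, see [defaultVolumes()].
#' @export
writeDropletCsv <- function(dropletData, file) {
    data.table::fwrite(dropletTable(dropletData), file)
    invisible(file)
}

#' @rdname writeDropletCsv
#' @export
readDropletCsv <- function(file, volumes = defaultVolumes()) {
    DropletData(data.table::fread(file), volumes)
}

#' Persist / restore the detection model state
#'
#' The model state is everything needed to score a new cohort with zero
#' refitting: the marker panel, per-marker amplitude thresholds and
#' copies/ml cutoffs, the log-conversion epsilon, the volume chain, and the
#' selected linear model with its decision cutoff.
#'
#' @param state list with elements `panel` ([MarkerPanel-class]),
#'   `thresholds` (named list of [AmplitudeThresholds-class]), `cutoffs`
#'   (named numeric), `epsilon`, `volumes`, and optionally `model`
#'   (a [LinearDetectionModel-class]).
#' @param file JSON path.
#' @return `readModelState` returns the state list with classes restored.
#' @export
writeModelState <- function(state, file) {
    ser <- list(
        panel = list(methylationMarkers = methylationMarkers(state$panel),
                     internalControls = internalControls(state$panel),
                     channelMap = as.list(state$panel@channelMap)),
        thresholds = lapply(state$thresholds, function(t)
            list(lower = t@lower, upper = t@upper,
                 achievedAUC = t@achievedAUC)),
        cutoffs = as.list(state$cutoffs),
        epsilon = state$epsilon,
        volumes = state$volumes)
    if (!is.null(state$model)) {
        m <- state$model
        ser$model <- list(variableNames = m@variableNames,
                          weights = as.list(m@weights),
                          intercept = m@intercept,
                          decisionCutoff = m@decisionCutoff)
    }
    jsonlite::write_json(ser, file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}

#' @rdname writeModelState
#' @export
readModelState <- function(file) {
    ser <- jsonlite::read_json(file, simplifyVector = FALSE)
    state <- list(
        panel = MarkerPanel(
            unlist(ser$panel$methylationMarkers),
            unlist(ser$panel$internalControls),
            unlist(ser$panel$channelMap)),
        thresholds = lapply(ser$thresholds, function(t)
            AmplitudeThresholds(t$lower, t$upper,
                                if (is.null(t$achievedAUC)) NA_real_
                                else t$achievedAUC)),
        cutoffs = unlist(ser$cutoffs),
        epsilon = ser$epsilon,
        volumes = ser$volumes)
    if (!is.null(ser$model))
        state$model <- LinearDetectionModel(
            unlist(ser$model$variableNames),
            unlist(ser$model$weights),
            ser$model$intercept, ser$model$decisionCutoff)
    state
}
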