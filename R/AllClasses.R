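#' @import methods
#' @importFrom stats quantile rnorm runif rpois rbinom sd pnorm
#'   t.test kruskal.test cor.test median setNames coef predict
#' @importFrom utils head combn
#' @importFrom data.table data.table as.data.table rbindlist fread fwrite
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
NULL

.datatable.aware <- TRUE

.ARRAY_GROUPS <- c("BC-luminal", "BC-TN", "BC-other", "non-BC")
.ARRAY_MATERIALS <- c("cell-line", "FFPE", "blood", "epithelia")

#' Beta-value methylation array experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container for an
#' Infinium-style beta-value matrix (probes x samples, values in \[0, 1\])
#' whose samples carry the two annotations candidate-marker selection needs: a
#' `group` (`"BC-luminal"`, `"BC-TN"`, `"BC-other"` or `"non-BC"`) and a
#' `material` (`"cell-line"`, `"FFPE"`, `"blood"` or `"epithelia"`).
#'
#' @slot .Data inherited `SummarizedExperiment` with one assay, `"beta"`.
#' @seealso [BetaArrayExperiment()] (constructor), [computeGroupMeans()],
#'   [selectCandidates()]
#' @exportClass BetaArrayExperiment
setClass("BetaArrayExperiment", contains = "SummarizedExperiment")

setValidity("BetaArrayExperiment", function(object) {
    msg <- character()
    if (!"beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "beta")
        if (anyNA(b)) msg <- c(msg, "beta values must not be missing")
        else if (min(b) < 0 || max(b) > 1)
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    cd <- SummarizedExperiment::colData(object)
    for (col in c("group", "material"))
        if (!col %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if ("group" %in% colnames(cd) &&
        !all(cd$group %in% .ARRAY_GROUPS))
        msg <- c(msg, "unknown sample group label")
    if ("material" %in% colnames(cd) &&
        !all(cd$material %in% .ARRAY_MATERIALS))
        msg <- c(msg, "unknown sample material label")
    if (length(msg)) msg else TRUE
})

#' Construct a BetaArrayExperiment
#'
#' @param beta numeric matrix of beta values, probes in rows, samples in
#'   columns; rownames are probe identifiers, colnames sample identifiers.
#' @param group character vector, one of `"BC-luminal"`, `"BC-TN"`,
#'   `"BC-other"`, `"non-BC"` per sample.
#' @param material character vector, one of `"cell-line"`, `"FFPE"`,
#'   `"blood"`, `"epithelia"` per sample.
#' @return A [BetaArrayExperiment-class] object.
#' @examples
#' beta <- matrix(runif(20, 0, 0.04), 5, 4,
#'                dimnames = list(paste0("cg", 1:5), paste0("s", 1:4)))
#' ae <- BetaArrayExperiment(beta,
#'                           group = c("BC-luminal", "BC-TN", rep("non-BC", 2)),
#'                           material = c("cell-line", "FFPE", "blood", "blood"))
#' @export
BetaArrayExperiment <- function(beta, group, material) {
    beta <- as.matrix(beta)
    if (is.null(rownames(beta)))
        rownames(beta) <- sprintf("probe%06d", seq_len(nrow(beta)))
    if (is.null(colnames(beta)))
        colnames(beta) <- sprintf("sample%03d", seq_len(ncol(beta)))
    stopifnot(length(group) == ncol(beta), length(material) == ncol(beta))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(beta = beta),
        colData = S4Vectors::DataFrame(group = as.character(group),
                                       material = as.character(material),
                                       row.names = colnames(beta)))
    new("BetaArrayExperiment", se)
}

#' @export
setMethod("show", "BetaArrayExperiment", function(object) {
    cat("BetaArrayExperiment:", nrow(object), "probes x",
        ncol(object), "samples\n")
    cat("  groups:   ",
        paste(sprintf("%s(%d)", names(table(object$group)),
                      table(object$group)), collapse = " "), "\n")
    cat("  materials:",
        paste(sprintf("%s(%d)", names(table(object$material)),
                      table(object$material)), collapse = " "), "\n")
})

#' ddMSP marker panel
#'
#' The marker panel of a duplex ddMSP assay: methylation markers whose
#' methylated-fragment concentration is quantified, internal-control markers
#' (CpG-free amplicons measuring total cfDNA irrespective of methylation
#' status), and the fluorescence channel each marker is read on.
#'
#' @slot methylationMarkers character, methylation marker identifiers.
#' @slot internalControls character, internal-control marker identifiers.
#' @slot channelMap named character, channel label per marker.
#' @exportClass MarkerPanel
setClass("MarkerPanel",
         representation(methylationMarkers = "character",
                        internalControls = "character",
                        channelMap = "character"))

setValidity("MarkerPanel", function(object) {
    all_mk <- c(object@methylationMarkers, object@internalControls)
    msg <- character()
    if (anyDuplicated(all_mk)) msg <- c(msg, "marker identifiers must be distinct")
    if (!all(all_mk %in% names(object@channelMap)))
        msg <- c(msg, "every marker needs a channel assignment")
    if (length(msg)) msg else TRUE
})

.PUBLISHED_METH_MARKERS <- c("JAK3", "RASGRF1", "CPXM1", "SHF",
                             "DNM3", "CAV2", "HOXA10", "B3GNT5",
                             "ST3GAL6", "DACH1", "P2RX3", "chr8_23572595")
.PUBLISHED_IC_MARKERS <- c("CREM", "GLYATL3", "ELMOD3", "KLF9")

#' Construct a MarkerPanel
#'
#' The default is the published 16-marker breast-cancer panel: four common
#' markers (JAK3, RASGRF1, CPXM1, SHF), four luminal-dominant (DNM3, CAV2,
#' HOXA10, B3GNT5), four TN-dominant (ST3GAL6, DACH1, P2RX3, chr8_23572595)
#' and four internal controls (CREM, GLYATL3, ELMOD3, KLF9).
#'
#' @param methylationMarkers character vector of methylation marker ids.
#' @param internalControls character vector of internal-control marker ids.
#' @param channelMap optional named character vector assigning a fluorescence
#'   channel to every marker; by default markers alternate FAM/HEX in duplex
#'   pairs.
#' @return A [MarkerPanel-class].
#' @export
MarkerPanel <- function(methylationMarkers = .PUBLISHED_METH_MARKERS,
                        internalControls = .PUBLISHED_IC_MARKERS,
                        channelMap = NULL) {
    all_mk <- c(methylationMarkers, internalControls)
    if (is.null(channelMap))
        channelMap <- setNames(
            rep(c("FAM", "HEX"), length.out = length(all_mk)), all_mk)
    new("MarkerPanel", methylationMarkers = methylationMarkers,
        internalControls = internalControls, channelMap = channelMap)
}

#' @describeIn MarkerPanel methylation marker identifiers.
#' @param panel a `MarkerPanel`.
#' @export
methylationMarkers <- function(panel) panel@methylationMarkers

#' @describeIn MarkerPanel internal-control marker identifiers.
#' @export
internalControls <- function(panel) panel@internalControls

#' @export
setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel:", length(object@methylationMarkers),
        "methylation +", length(object@internalControls),
        "internal-control markers\n")
    cat("  methylation:", paste(object@methylationMarkers, collapse = ", "), "\n")
    cat("  controls:   ", paste(object@internalControls, collapse = ", "), "\n")
})

#' Droplet amplitude thresholds
#'
#' The lower and upper amplitude cutoffs that define a positive droplet
#' (amplitude in the half-open interval `(lower, upper]`), together with the
#' single-marker ROC AUC achieved on the training samples when the thresholds
#' were optimised.
#'
#' @slot lower,upper numeric amplitude cutoffs, `lower < upper`.
#' @slot achievedAUC numeric, training AUC of the marker at these thresholds.
#' @exportClass AmplitudeThresholds
setClass("AmplitudeThresholds",
         representation(lower = "numeric", upper = "numeric",
                        achievedAUC = "numeric"))

setValidity("AmplitudeThresholds", function(object) {
    if (object@lower >= object@upper) "lower must be < upper" else TRUE
})

#' @rdname AmplitudeThresholds-class
#' @param lower,upper amplitude cutoffs.
#' @param achievedAUC AUC achieved by these thresholds (NA if never scored).
#' @export
AmplitudeThresholds <- function(lower, upper, achievedAUC = NA_real_) {
    new("AmplitudeThresholds", lower = as.numeric(lower),
        upper = as.numeric(upper), achievedAUC = as.numeric(achievedAUC))
}

#' @export
setMethod("show", "AmplitudeThresholds", function(object) {
    cat(sprintf("AmplitudeThresholds: (%.4g, %.4g], AUC = %.4g\n",
                object@lower, object@upper, object@achievedAUC))
})

#' Linear detection-index model
#'
#' A linear decision function over a subset of the 15 per-sample variables:
#' `index = sum(weights * variables) + intercept`, with samples called
#' positive when the index strictly exceeds `decisionCutoff`.
#'
#' @slot variableNames character, variables entering the model.
#' @slot weights numeric, one weight per variable.
#' @slot intercept numeric scalar.
#' @slot decisionCutoff numeric scalar; positivity is strict (`index > cutoff`).
#' @seealso [fixedPublishedModel()], [detectionIndex()], [classifyIndex()]
#' @exportClass LinearDetectionModel
setClass("LinearDetectionModel",
         representation(variableNames = "character", weights = "numeric",
                        intercept = "numeric", decisionCutoff = "numeric"))

setValidity("LinearDetectionModel", function(object) {
    msg <- character()
    if (length(object@weights) != length(object@variableNames))
        msg <- c(msg, "one weight per variable is required")
    if (length(object@intercept) != 1L) msg <- c(msg, "intercept must be scalar")
    if (length(msg)) msg else TRUE
})

#' @rdname LinearDetectionModel-class
#' @param variableNames,weights,intercept,decisionCutoff see slots.
#' @export
LinearDetectionModel <- function(variableNames, weights, intercept,
                                 decisionCutoff = 0) {
    new("LinearDetectionModel",
        variableNames = as.character(variableNames),
        weights = setNames(as.numeric(weights), variableNames),
        intercept = as.numeric(intercept),
        decisionCutoff = as.numeric(decisionCutoff))
}

#' @describeIn LinearDetectionModel-class variable names of the model.
#' @param object,model a `LinearDetectionModel`.
#' @export
variableNames <- function(model) model@variableNames

#' @describeIn LinearDetectionModel-class decision cutoff of the model.
#' @export
decisionCutoff <- function(model) model@decisionCutoff

#' @describeIn LinearDetectionModel-class intercept of the model.
#' @export
modelIntercept <- function(model) model@intercept

#' @describeIn LinearDetectionModel-class named weight vector.
#' @param ... ignored.
#' @export
setMethod("coef", "LinearDetectionModel", function(object, ...)
    object@weights)

#' @export
setMethod("show", "LinearDetectionModel", function(object) {
    cat("LinearDetectionModel over",
        length(object@variableNames), "variables\n")
    terms <- sprintf("%+.5f*[%s]", object@weights, object@variableNames)
    cat("  index =", paste(terms, collapse = " "),
        sprintf("%+.5f\n", object@intercept))
    cat(sprintf("  positive iff index > %.5f\n", object@decisionCutoff))
})

#' The fixed published breast-cancer detection model
#'
#' The six-variable linear detection index reported for the cfDNA ddMSP
#' breast-cancer assay:
#' \deqn{0.62449 [RASGRF1] + 0.78110 [CPXM1] + 0.12115 [HOXA10] +
#'   0.36760 [DACH1] + 0.65288 [Mean12] + 2.44704 [IC] - 6.98073}
#' with samples called positive when the index strictly exceeds -0.07923.
#' The four gene variables are log10 methylated-fragment concentrations
#' (copies/ml plasma), `Mean12` the mean of all 12 marker log10
#' concentrations, and `IC` the log10 geometric-mean internal-control
#' concentration.
#'
#' @return A [LinearDetectionModel-class] carrying the verbatim published
#'   coefficients.
#' @examples
#' m <- fixedPublishedModel()
#' detectionIndex(m, data.frame(RASGRF1 = 0, CPXM1 = 0, HOXA10 = 0,
#'                              DACH1 = 0, Mean12 = 0, IC = 0))  # -6.98073
#' @export
fixedPublishedModel <- function() {
    LinearDetectionModel(
        variableNames = c("RASGRF1", "CPXM1", "HOXA10", "DACH1",
                          "Mean12", "IC"),
        weights = c(0.62449, 0.78110, 0.12115, 0.36760, 0.65288, 2.44704),
        intercept = -6.98073,
        decisionCutoff = -0.07923)
}

#' Result of the exhaustive variable-combination search
#'
#' @slot table data.frame with one row per variable combination: `mask`
#'   (0/1 string over the searched variables), `nVariables`, `loocvAUC`,
#'   `allWeightsPositive`.
#' @slot best the winning [LinearDetectionModel-class] (full-data refit).
#' @slot bestLoocvAUC LOOCV AUC of the winning combination.
#' @slot constraintSatisfied logical; `FALSE` when no combination had an
#'   all-positive full-data refit and the unconstrained best is returned.
#' @slot variables character, the variables that were searched (mask order).
#' @exportClass DetectionSearchResult
setClass("DetectionSearchResult",
         representation(table = "data.frame", best = "LinearDetectionModel",
                        bestLoocvAUC = "numeric",
                        constraintSatisfied = "logical",
                        variables = "character"))

#' @export
setMethod("show", "DetectionSearchResult", function(object) {
    cat("DetectionSearchResult:", nrow(object@table), "combinations over",
        length(object@variables), "variables\n")
    cat(sprintf("  best LOOCV AUC = %.4f (%s)%s\n", object@bestLoocvAUC,
                paste(object@best@variableNames, collapse = "+"),
                if (object@constraintSatisfied) ""
                else "  [positivity constraint NOT met]"))
})

#' @describeIn DetectionSearchResult-class per-combination search table.
#' @param x a `DetectionSearchResult`.
#' @export
searchTable <- function(x) x@table

#' @describeIn DetectionSearchResult-class winning model.
#' @export
bestModel <- function(x) x@best

#' Droplet-level ddMSP dataset
#'
#' Droplet fluorescence amplitudes in long format plus the volume chain needed
#' to turn positive-droplet counts into copies/ml plasma.
#'
#' @slot droplets a `data.table` with columns `sample_id`, `marker`, `well`,
#'   `channel`, `amplitude`.
#' @slot volumes named list: `dropletVolumeNl`, `reactionTemplateVolumeUl`,
#'   `elutionVolumeUl`, `plasmaVolumeMl`.
#' @exportClass DropletData
setClass("DropletData",
         representation(droplets = "data.frame", volumes = "list"))

setValidity("DropletData", function(object) {
    need <- c("sample_id", "marker", "well", "channel", "amplitude")
    msg <- character()
    if (!all(need %in% colnames(object@droplets)))
        msg <- c(msg, paste("droplet table needs columns:",
                            paste(need, collapse = ", ")))
    vn <- c("dropletVolumeNl", "reactionTemplateVolumeUl",
            "elutionVolumeUl", "plasmaVolumeMl")
    if (!all(vn %in% names(object@volumes)))
        msg <- c(msg, "incomplete volume specification")
    else if (any(unlist(object@volumes[vn]) <= 0))
        msg <- c(msg, "volumes must be positive")
    if (length(msg)) msg else TRUE
})

#' Default ddMSP volume chain
#'
#' 0.85 nl droplets, 2 ul template per 20 ul reaction, ~20 ul elution from
#' 0.9 ml plasma.
#'
#' @return Named list of the four volumes.
#' @export
defaultVolumes <- function() {
    list(dropletVolumeNl = 0.85, reactionTemplateVolumeUl = 2,
         elutionVolumeUl = 20, plasmaVolumeMl = 0.9)
}

#' @rdname DropletData-class
#' @param droplets long-format droplet table (`sample_id`, `marker`, `well`,
#'   `channel`, `amplitude`).
#' @param volumes volume chain, see [defaultVolumes()].
#' @export
DropletData <- function(droplets, volumes = defaultVolumes()) {
    new("DropletData", droplets = data.table::as.data.table(droplets),
        volumes = volumes)
}

#' @describeIn DropletData-class the long droplet table.
#' @param x a `DropletData`.
#' @export
dropletTable <- function(x) x@droplets

#' @describeIn DropletData-class the volume chain.
#' @export
dropletVolumes <- function(x) x@volumes

#' @export
setMethod("show", "DropletData", function(object) {
    dt <- object@droplets
    cat("DropletData:", nrow(dt), "droplets,",
        length(unique(dt$sample_id)), "samples x",
        length(unique(dt$marker)), "markers\n")
})
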