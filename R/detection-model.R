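## Linear SVM detection models: fitting, the detection index, LOOCV scoring
## and the exhaustive variable-combination search.
##
## The detection model is a soft-margin linear SVM on unstandardised
## features, so its weights live on the same scale as the printed published
## equation. Model selection enumerates every nonempty variable subset
## (2^V - 1), scores each by the AUC of pooled leave-one-out decision
## values, and accepts the best-scoring subset whose full-data refit has all
## weights strictly positive.

#' Evaluate the detection index
#'
#' `index = sum(weights * variables) + intercept` for each row of the
#' feature table. All model variables must be present.
#'
#' @param model a [LinearDetectionModel-class].
#' @param features data.frame/matrix of feature values (columns named as the
#'   model variables), or a single named vector.
#' @return numeric vector of detection indexes.
#' @examples
#' detectionIndex(fixedPublishedModel(),
#'                c(RASGRF1 = 0, CPXM1 = 0, HOXA10 = 0, DACH1 = 0,
#'                  Mean12 = 0, IC = 0))  # -6.98073
#' @export
detectionIndex <- function(model, features) {
    stopifnot(is(model, "LinearDetectionModel"))
    vars <- model@variableNames
    if (length(vars) == 0) {
        n <- if (is.null(dim(features))) 1L else nrow(features)
        return(rep(model@intercept, n))
    }
    if (is.null(dim(features)))
        features <- as.data.frame(as.list(features), check.names = FALSE)
    missing <- setdiff(vars, colnames(features))
    if (length(missing))
        stop("feature table lacks model variable(s): ",
             paste(missing, collapse = ", "))
    x <- as.matrix(features[, vars, drop = FALSE])
    as.vector(x %*% model@weights) + model@intercept
}

#' Classify a detection index
#'
#' Positive iff the index strictly exceeds the cutoff ("more than"); an
#' index exactly at the cutoff is negative.
#'
#' @param index numeric detection indexes.
#' @param cutoff decision cutoff (default: the published -0.07923).
#' @return character vector of `"positive"` / `"negative"`.
#' @examples
#' classifyIndex(c(-0.07923, 0))  # "negative" "positive"
#' @export
classifyIndex <- function(index, cutoff = -0.07923) {
    ifelse(index > cutoff, "positive", "negative")
}

.asLabelFactor <- function(labels, positive = "BC") {
    labels <- as.character(labels)
    lv <- unique(labels)
    if (!positive %in% lv) stop("positive class '", positive, "' absent")
    factor(labels, levels = c(setdiff(lv, positive), positive))
}

#' Fit a linear soft-margin SVM detection model
#'
#' Wraps [e1071::svm()] with a linear kernel on unstandardised features and
#' extracts the primal weights and intercept, oriented so that a larger
#' decision value means more likely `positive`. The returned
#' [LinearDetectionModel-class] reproduces the SVM decision values exactly
#' via [detectionIndex()].
#'
#' @param features data.frame/matrix of predictors.
#' @param labels class labels (two classes required).
#' @param cost soft-margin regularisation parameter C (default 1).
#' @param positive positive class label (default `"BC"`).
#' @param decisionCutoff cutoff stored on the model (default 0, the SVM
#'   decision boundary).
#' @return A [LinearDetectionModel-class].
#' @export
fitLinearSVM <- function(features, labels, cost = 1, positive = "BC",
                         decisionCutoff = 0) {
    x <- as.matrix(features)
    y <- .asLabelFactor(labels, positive)
    if (nlevels(droplevels(y)) < 2)
        stop("both classes are required to fit the SVM")
    fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    ## libsvm decision values are positive for the first class of the
    ## decision-value column name; orient toward `positive`
    dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
               "decision.values")
    firstClass <- strsplit(colnames(dv), "/")[[1]][1]
    if (firstClass != positive) {
        w <- -w
        b <- -b
    }
    LinearDetectionModel(colnames(x), unname(w), b, decisionCutoff)
}

#' Leave-one-out cross-validated decision values
#'
#' For each sample, fits the SVM on all other samples and records the
#' held-out sample's decision value. The AUC of these pooled out-of-fold
#' values is the LOOCV score of the variable set.
#'
#' @inheritParams fitLinearSVM
#' @return numeric vector of out-of-fold decision values, one per row.
#' @export
loocvScores <- function(features, labels, cost = 1, positive = "BC") {
    x <- as.matrix(features)
    labels <- as.character(labels)
    n <- nrow(x)
    tab <- table(labels)
    if (length(tab) < 2 || min(tab) < 3)
        stop("at least 3 samples per class are required for LOOCV")
    scores <- numeric(n)
    for (i in seq_len(n)) {
        if (length(unique(labels[-i])) < 2)
            stop("a LOOCV fold has single-class training labels")
        m <- fitLinearSVM(x[-i, , drop = FALSE], labels[-i], cost = cost,
                          positive = positive)
        scores[i] <- detectionIndex(m, x[i, , drop = FALSE])
    }
    scores
}

#' Enumerate nonempty variable-subset masks
#'
#' The search space of the exhaustive combination search: all `2^V - 1`
#' nonempty subsets of `V` variables, as a logical matrix in enumeration
#' order (mask `j` includes variable `k` iff bit `k-1` of `j` is set).
#'
#' @param nVariables number of variables V (1..30).
#' @return logical matrix, `2^V - 1` rows x `V` columns.
#' @examples
#' nrow(enumerateVariableMasks(15))  # 32767
#' @export
enumerateVariableMasks <- function(nVariables) {
    stopifnot(nVariables >= 1, nVariables <= 30)
    j <- seq_len(2^nVariables - 1)
    masks <- vapply(seq_len(nVariables),
                    function(k) bitwAnd(j, bitwShiftL(1L, k - 1L)) > 0,
                    logical(length(j)))
    matrix(masks, nrow = length(j), ncol = nVariables)
}

#' Exhaustive variable-combination search with LOOCV
#'
#' Enumerates all nonempty subsets of `variables`, scores each by the AUC of
#' pooled LOOCV decision values, refits each candidate on the full training
#' set, and selects the best-AUC subset whose refit weights are all strictly
#' positive. Ties resolve to fewer variables, then lexicographic mask order.
#' If no subset satisfies the positivity constraint, the unconstrained best
#' is returned with `constraintSatisfied = FALSE`.
#'
#' The winning model's decision cutoff is set by the Youden rule on its
#' full-training-set detection indexes.
#'
#' @param features feature table (data.frame) containing `variables`.
#' @param labels HV/BC labels per row.
#' @param variables character vector of variables to search over (mask bit
#'   order); default all 15.
#' @param cost SVM regularisation parameter.
#' @param positive positive class label.
#' @param verbose print progress every 500 combinations.
#' @return A [DetectionSearchResult-class].
#' @export
exhaustiveSearch <- function(features, labels,
                             variables = featureVariableNames(),
                             cost = 1, positive = "BC", verbose = FALSE) {
    stopifnot(length(variables) >= 1, length(variables) <= 15,
              all(variables %in% colnames(features)))
    x <- as.matrix(features[, variables, drop = FALSE])
    masks <- enumerateVariableMasks(length(variables))
    nC <- nrow(masks)
    auc <- numeric(nC)
    allPos <- logical(nC)
    y <- as.character(labels)
    for (j in seq_len(nC)) {
        sel <- masks[j, ]
        xs <- x[, sel, drop = FALSE]
        auc[j] <- rocAuc(loocvScores(xs, y, cost, positive), y,
                         positive = positive)
        refit <- fitLinearSVM(xs, y, cost, positive)
        allPos[j] <- all(refit@weights > 0)
        if (verbose && j %% 500 == 0)
            message("  searched ", j, "/", nC, " combinations")
    }
    maskStr <- apply(masks, 1, function(m) paste(as.integer(m), collapse = ""))
    tab <- data.frame(mask = maskStr, nVariables = rowSums(masks),
                      loocvAUC = auc, allWeightsPositive = allPos,
                      stringsAsFactors = FALSE)
    pickBest <- function(idx) {
        cand <- idx[auc[idx] == max(auc[idx])]
        cand <- cand[tab$nVariables[cand] == min(tab$nVariables[cand])]
        cand[order(tab$mask[cand])][1]
    }
    satisfied <- any(allPos)
    best <- if (satisfied) pickBest(which(allPos)) else pickBest(seq_len(nC))
    if (!satisfied)
        warning("no variable combination had an all-positive refit; ",
                "returning the unconstrained best", call. = FALSE)
    sel <- masks[best, ]
    model <- fitLinearSVM(x[, sel, drop = FALSE], y, cost, positive)
    idxTrain <- detectionIndex(model, features)
    model@decisionCutoff <- determineMarkerCutoff(idxTrain, y,
                                                  positive = positive)$cutoff
    new("DetectionSearchResult", table = tab, best = model,
        bestLoocvAUC = auc[best], constraintSatisfied = satisfied,
        variables = variables)
}
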