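## Evaluation statistics: Mann-Whitney AUC, confusion metrics at the strict
## cutoff, stratified train/validation splitting, the Jonckheere-Terpstra
## ordered trend test, and the stage/subtype/age subgroup report.

#' Mann-Whitney ROC AUC
#'
#' Rank-based AUC: the probability that a random positive scores above a
#' random negative, with tied score pairs contributing 1/2.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels class labels (or logicals) aligned with `scores`.
#' @param positive positive class label (`TRUE` when labels are logical).
#' @return AUC in \[0, 1\].
#' @examples
#' rocAuc(c(1, 2, 3, 4), c("HV", "HV", "BC", "BC"))  # 1
#' @export
rocAuc <- function(scores, labels, positive = "BC") {
    y <- if (is.logical(labels)) labels else as.character(labels) == positive
    n1 <- sum(y); n0 <- sum(!y)
    if (n1 == 0 || n0 == 0) stop("both classes are required for the AUC")
    r <- rank(scores)  # average ranks: ties count 1/2
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a cutoff
#'
#' Positivity is strict: a sample is called positive iff its score exceeds
#' the cutoff, consistent with [classifyIndex()].
#'
#' @param scores numeric detection indexes.
#' @param labels class labels.
#' @param cutoff decision cutoff.
#' @param positive positive class label.
#' @return list with the 2x2 counts (`tp`, `fn`, `tn`, `fp`) and
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusionAtCutoff <- function(scores, labels, cutoff = -0.07923,
                              positive = "BC") {
    y <- if (is.logical(labels)) labels else as.character(labels) == positive
    if (!any(y) || all(y)) stop("both classes are required")
    call <- scores > cutoff
    tp <- sum(call & y); fn <- sum(!call & y)
    fp <- sum(call & !y); tn <- sum(!call & !y)
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         accuracy = (tp + tn) / (tp + fn + fp + tn))
}

#' Stratified train/validation split
#'
#' Assigns each roster sample to `"train"` or `"validation"` within strata
#' defined by (class, stage); within each stratum, `round(n * fraction)`
#' samples are drawn for training. Deterministic given `seed`. A stratum of
#' size one goes to training with a warning.
#'
#' @param roster a roster data.frame (`class`, `stage` columns; see
#'   [simulateRoster()]).
#' @param trainFraction scalar fraction, or named vector keyed
#'   `"class:stage"` (e.g. `"BC:IIA"`, `"HV:none"`).
#' @param seed integer seed for the within-stratum draw.
#' @return the roster with its `split` column filled in.
#' @export
stratifiedSplit <- function(roster, trainFraction = 0.6, seed = 1L) {
    set.seed(as.integer(seed))
    key <- paste(roster$class, roster$stage, sep = ":")
    roster$split <- NA_character_
    for (k in unique(key)) {
        idx <- which(key == k)
        f <- if (length(trainFraction) == 1 && is.null(names(trainFraction)))
            trainFraction
        else if (k %in% names(trainFraction)) trainFraction[[k]]
        else stop("no train fraction for stratum ", k)
        if (length(idx) == 1) {
            warning("stratum ", k, " has a single sample; assigned to train",
                    call. = FALSE)
            roster$split[idx] <- "train"
            next
        }
        nTrain <- round(length(idx) * f)
        tr <- idx[sample.int(length(idx), nTrain)]
        roster$split[idx] <- "validation"
        roster$split[tr] <- "train"
    }
    roster
}

#' Published train/validation stratum fractions
#'
#' The per-stratum training fractions of the published cohort: 80/133 HVs
#' and, by stage, 3/4, 27/47, 19/31, 11/22, 8/9, 19/32 BC patients, giving a
#' 167-sample training and 111-sample validation set on the published
#' roster.
#'
#' @return named numeric vector keyed `"class:stage"`.
#' @export
table1SplitFractions <- function() {
    c("HV:none" = 80 / 133, "BC:0" = 3 / 4, "BC:I" = 27 / 47,
      "BC:IIA" = 19 / 31, "BC:IIB" = 11 / 22, "BC:III" = 8 / 9,
      "BC:IV" = 19 / 32)
}

.jtStatistic <- function(values, groups) {
    lv <- levels(groups)
    jt <- 0
    for (i in seq_len(length(lv) - 1)) {
        xi <- values[groups == lv[i]]
        for (j in seq(i + 1, length(lv))) {
            xj <- values[groups == lv[j]]
            d <- outer(xi, xj, function(a, b) (a < b) + 0.5 * (a == b))
            jt <- jt + sum(d)
        }
    }
    jt
}

## exact null distribution by enumerating all distinct assignments of the
## observed values to the group sizes
.jtExactP <- function(values, groups, observed, upper = TRUE) {
    sizes <- table(groups)
    lv <- levels(groups)
    n <- length(values)
    count <- c(total = 0, extreme = 0)
    recurse <- function(remaining, gi, assignment) {
        if (gi == length(lv)) {
            assignment[remaining] <- lv[gi]
            g <- factor(assignment, levels = lv)
            jt <- .jtStatistic(values, g)
            count["total"] <<- count["total"] + 1
            hit <- if (upper) jt >= observed - 1e-9 else jt <= observed + 1e-9
            if (hit) count["extreme"] <<- count["extreme"] + 1
            return(invisible())
        }
        for (pick in asplit(combn(remaining, sizes[gi]), 2)) {
            assignment[pick] <- lv[gi]
            recurse(setdiff(remaining, pick), gi + 1, assignment)
        }
    }
    recurse(seq_len(n), 1, character(n))
    unname(count["extreme"] / count["total"])
}

#' Jonckheere-Terpstra ordered trend test
#'
#' Tests for a monotone trend of `values` across ordered `groups`. The
#' statistic is the sum of pairwise Mann-Whitney counts over ordered group
#' pairs (ties count 1/2). p values use the normal approximation with the
#' tie-corrected variance and a 0.5 continuity correction; for small samples
#' (`n <= 12` by default) an exact permutation p value is available.
#'
#' @param values numeric observations.
#' @param groups ordered factor (or vector coerced in level order) giving
#'   each observation's group; at least two nonempty groups.
#' @param alternative `"increasing"` (default: later groups have larger
#'   values), `"decreasing"`, or `"two.sided"`.
#' @param exact `TRUE`/`FALSE`, or `NULL` to choose exact enumeration
#'   automatically when `length(values) <= 12`.
#' @return list with `statistic`, `z`, `p.value` and `method`.
#' @examples
#' jonckheereTerpstra(c(1, 2, 3), factor(c("a", "b", "c"),
#'                    levels = c("a", "b", "c")))
#' @export
jonckheereTerpstra <- function(values, groups,
                               alternative = c("increasing", "decreasing",
                                               "two.sided"),
                               exact = NULL) {
    alternative <- match.arg(alternative)
    if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
    groups <- droplevels(groups)
    if (nlevels(groups) < 2) stop("at least two nonempty groups are required")
    if (any(table(groups) == 0)) stop("every group must be nonempty")
    n <- length(values)
    stopifnot(length(groups) == n)
    jt <- .jtStatistic(values, groups)
    ni <- as.numeric(table(groups))
    muJT <- (n^2 - sum(ni^2)) / 4
    tj <- as.numeric(table(values))  # tie group sizes
    s1 <- n * (n - 1) * (2 * n + 5) -
        sum(ni * (ni - 1) * (2 * ni + 5)) -
        sum(tj * (tj - 1) * (2 * tj + 5))
    s2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    s3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    varJT <- s1 / 72 +
        s2 / (36 * n * (n - 1) * (n - 2)) +
        s3 / (8 * n * (n - 1))
    if (is.null(exact)) exact <- n <= 12
    if (exact && n > 14)
        stop("exact enumeration supported for n <= 14 only")
    if (exact) {
        p <- switch(alternative,
            increasing = .jtExactP(values, groups, jt, upper = TRUE),
            decreasing = .jtExactP(values, groups, jt, upper = FALSE),
            two.sided = min(1, 2 * min(
                .jtExactP(values, groups, jt, upper = TRUE),
                .jtExactP(values, groups, jt, upper = FALSE))))
        method <- "exact permutation"
        z <- (jt - muJT) / sqrt(varJT)
    } else {
        ## continuity-corrected normal approximation
        cc <- 0.5
        z <- (jt - muJT) / sqrt(varJT)
        zUp <- (jt - cc - muJT) / sqrt(varJT)
        zDown <- (jt + cc - muJT) / sqrt(varJT)
        p <- switch(alternative,
            increasing = pnorm(zUp, lower.tail = FALSE),
            decreasing = pnorm(zDown),
            two.sided = min(1, 2 * min(pnorm(zUp, lower.tail = FALSE),
                                       pnorm(zDown))))
        method <- "normal approximation (tie-corrected, continuity-corrected)"
    }
    list(statistic = jt, z = z, p.value = p, method = method)
}

.DEFAULT_STAGE_BUCKETS <- list("0-I" = c("0", "I"), "IIA" = "IIA",
                               "IIB-III" = c("IIB", "III"), "MBC" = "IV")

#' Stage and subtype subgroup report
#'
#' For each stage bucket (default 0-I, IIA, IIB-III, MBC) and each subtype:
#' sample count, sensitivity at the cutoff, and the AUC of that BC subgroup
#' against all HVs in the supplied set. Also reports the Kruskal-Wallis
#' p value of the detection index across subtypes (BC only), the
#' Jonckheere-Terpstra trend p across stage buckets, and the Pearson
#' correlation of age with the detection index among BC samples.
#'
#' @param scores detection indexes aligned with `roster` rows.
#' @param roster roster data.frame (`class`, `stage`, `subtype`, `age`).
#' @param cutoff positivity cutoff (strict `>`).
#' @param stageBuckets named list mapping bucket label to stage values.
#' @return list with `byStage` and `bySubtype` data.frames (empty buckets
#'   have `n = 0` and `NA` metrics), `trendTest`, `subtypeTest`
#'   (Kruskal-Wallis htest or NULL), and `ageCorrelation`.
#' @export
subgroupReport <- function(scores, roster, cutoff = -0.07923,
                           stageBuckets = .DEFAULT_STAGE_BUCKETS) {
    stopifnot(length(scores) == nrow(roster))
    isBC <- roster$class == "BC"
    hvScores <- scores[!isBC]
    bucketOf <- rep(NA_character_, nrow(roster))
    for (b in names(stageBuckets))
        bucketOf[isBC & roster$stage %in% stageBuckets[[b]]] <- b
    rowFor <- function(sel) {
        n <- sum(sel)
        if (n == 0 || length(hvScores) == 0)
            return(c(n = n, sensitivity = NA_real_, auc = NA_real_))
        c(n = n,
          sensitivity = mean(scores[sel] > cutoff),
          auc = rocAuc(c(scores[sel], hvScores),
                       rep(c(TRUE, FALSE), c(n, length(hvScores))),
                       positive = TRUE))
    }
    byStage <- do.call(rbind, lapply(names(stageBuckets), function(b)
        data.frame(bucket = b, t(rowFor(!is.na(bucketOf) & bucketOf == b)))))
    subtypes <- setdiff(unique(roster$subtype[isBC]), NA)
    bySubtype <- do.call(rbind, lapply(sort(subtypes), function(s)
        data.frame(subtype = s, t(rowFor(isBC & roster$subtype == s)))))
    occupied <- names(stageBuckets)[names(stageBuckets) %in% bucketOf]
    trend <- if (length(occupied) >= 2)
        jonckheereTerpstra(scores[!is.na(bucketOf)],
                           factor(bucketOf[!is.na(bucketOf)],
                                  levels = names(stageBuckets)),
                           alternative = "increasing", exact = FALSE)
    else NULL
    subtypeTest <- if (length(subtypes) >= 2)
        kruskal.test(scores[isBC], factor(roster$subtype[isBC]))
    else NULL
    ageCor <- if (sum(isBC) >= 3)
        cor.test(roster$age[isBC], scores[isBC], method = "pearson")
    else NULL
    list(byStage = byStage, bySubtype = bySubtype,
         trendTest = trend, subtypeTest = subtypeTest,
         ageCorrelation = if (is.null(ageCor)) NULL else
             list(r = unname(ageCor$estimate), p = ageCor$p.value),
         metadata = list(
             stageAUCReference = "HVs of the same sample set"))
}

#' ROC curve points
#'
#' Sensitivity/specificity at every cutoff between consecutive sorted
#' unique scores (strict `>` positivity), plus the two degenerate
#' endpoints.
#'
#' @param scores numeric detection indexes.
#' @param labels class labels.
#' @param positive positive class label.
#' @return data.frame with columns `cutoff`, `sensitivity`, `specificity`.
#' @export
rocPoints <- function(scores, labels, positive = "BC") {
    y <- if (is.logical(labels)) labels else as.character(labels) == positive
    u <- sort(unique(scores))
    cuts <- c(min(u) - 1, (head(u, -1) + u[-1]) / 2, max(u))
    data.frame(
        cutoff = cuts,
        sensitivity = vapply(cuts, function(ct) mean(scores[y] > ct),
                             numeric(1)),
        specificity = vapply(cuts, function(ct) mean(scores[!y] <= ct),
                             numeric(1)))
}

#' Full evaluation report
#'
#' AUC, confusion metrics at the cutoff, and the subgroup analyses for one
#' scored cohort.
#'
#' @param scores detection indexes.
#' @param roster roster rows aligned with `scores` (needs `class`, `stage`,
#'   `subtype`, `age`).
#' @param cutoff positivity cutoff.
#' @return list: `auc`, confusion metrics, `subgroups`.
#' @export
evaluationReport <- function(scores, roster, cutoff = -0.07923) {
    cm <- confusionAtCutoff(scores, roster$class, cutoff)
    list(auc = rocAuc(scores, roster$class),
         sensitivity = cm$sensitivity, specificity = cm$specificity,
         ppv = cm$ppv, npv = cm$npv, accuracy = cm$accuracy,
         confusion = cm[c("tp", "fn", "tn", "fp")],
         cutoff = cutoff,
         subgroups = subgroupReport(scores, roster, cutoff))
}
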