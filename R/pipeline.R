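## Reproducible pipeline driver: a single validated configuration (YAML or
## list) ties the stages together -- simulate -> select-markers -> quantify
## -> features -> search/score -> evaluate -- with all artifacts written
## under one output directory, stamped with the configuration hash and seed.

.PIPELINE_STAGES <- c("simulate", "select-markers", "quantify", "features",
                      "search", "score", "evaluate")

.CONFIG_KEYS <- c("preset", "seed", "outdir", "epsilon", "cParam", "nGrid",
                  "searchVariables", "trainFraction", "useFixedModel",
                  "volumes", "arrayConfig", "cohortConfig")

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected (schema validation). The configuration can come
#' from a YAML file with the same keys.
#'
#' @param preset cohort preset name, see [cohortPreset()].
#' @param seed integer master seed for all stochastic stages.
#' @param outdir artifact directory (created on demand).
#' @param epsilon log10-conversion epsilon; `NULL` = [defaultEpsilon()].
#' @param cParam SVM soft-margin cost.
#' @param nGrid amplitude-threshold grid size.
#' @param searchVariables variables for [exhaustiveSearch()]; default the
#'   six published-model variables (a desk-scale search; the full 15 is
#'   supported but slow).
#' @param trainFraction per-stratum training fractions or scalar; `NULL` =
#'   [table1SplitFractions()] for the `table1_cohort` preset, 0.6 otherwise.
#' @param useFixedModel score with [fixedPublishedModel()] instead of a
#'   searched model.
#' @param volumes volume chain, see [defaultVolumes()].
#' @param arrayConfig named list of [arraySimConfig()] overrides.
#' @param cohortConfig named list of [cohortSimConfig()] overrides applied
#'   on top of the preset (e.g. a reduced `nDroplets` for desk-scale runs).
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(preset = "toy", seed = 1L,
                           outdir = tempfile("ddmsp_run_"),
                           epsilon = NULL, cParam = 1, nGrid = 64,
                           searchVariables = c("RASGRF1", "CPXM1", "HOXA10",
                                               "DACH1", "Mean12", "IC"),
                           trainFraction = NULL, useFixedModel = FALSE,
                           volumes = defaultVolumes(),
                           arrayConfig = list(), cohortConfig = list()) {
    cfg <- list(preset = preset, seed = as.integer(seed), outdir = outdir,
                epsilon = epsilon, cParam = cParam, nGrid = nGrid,
                searchVariables = searchVariables,
                trainFraction = trainFraction,
                useFixedModel = isTRUE(useFixedModel),
                volumes = volumes, arrayConfig = arrayConfig,
                cohortConfig = cohortConfig)
    class(cfg) <- "PipelineConfig"
    validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @param cfg a configuration list (e.g. parsed from YAML).
#' @export
validatePipelineConfig <- function(cfg) {
    unknown <- setdiff(names(cfg), .CONFIG_KEYS)
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    if (!cfg$preset %in% c("table1_cohort", "toy"))
        stop("unknown preset: ", cfg$preset)
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
        stop("seed must be a single integer")
    if (!is.null(cfg$epsilon) && cfg$epsilon < 0)
        stop("epsilon must be non-negative")
    if (cfg$cParam <= 0) stop("cParam must be positive")
    badVol <- setdiff(names(cfg$volumes),
                      names(defaultVolumes()))
    if (length(badVol))
        stop("unknown volume key(s): ", paste(badVol, collapse = ", "))
    badCoh <- setdiff(names(cfg$cohortConfig), names(formals(cohortSimConfig)))
    if (length(badCoh))
        stop("unknown cohortConfig key(s): ", paste(badCoh, collapse = ", "))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' @rdname pipelineConfig
#' @param file YAML file with configuration keys.
#' @export
readPipelineConfig <- function(file) {
    raw <- yaml::read_yaml(file)
    base <- pipelineConfig()
    for (k in names(raw)) base[[k]] <- raw[[k]]
    validatePipelineConfig(base)
}

## stable hash of the configuration: md5 of its canonical JSON
.configHash <- function(cfg) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    plain <- unclass(cfg)
    plain <- plain[order(names(plain))]
    jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
    unname(tools::md5sum(tmp))
}

.writeMeta <- function(cfg, stage, outdir, extra = list()) {
    meta <- c(list(stage = stage, preset = cfg$preset, seed = cfg$seed,
                   config_hash = .configHash(cfg),
                   timestamp = format(Sys.time(), tz = "UTC")),
              extra)
    jsonlite::write_json(meta, file.path(outdir,
                                         paste0(stage, ".meta.json")),
                         auto_unbox = TRUE, digits = NA)
}

#' Run the detection pipeline
#'
#' Executes the requested stages in canonical order (simulate ->
#' select-markers -> quantify -> features -> search/score -> evaluate),
#' writing each stage's artifacts (CSV/TSV/JSON) plus a metadata JSON
#' carrying the configuration hash and seed into `cfg$outdir`. Stages read
#' their inputs from the same directory, so a later stage can resume from an
#' earlier run; a missing upstream artifact is an error naming the stage to
#' run. An empty stage list is a no-op.
#'
#' Deterministic given the configuration: identical configs produce
#' identical artifacts.
#'
#' @param cfg a [pipelineConfig()] (or path to a YAML config).
#' @param stages subset of
#'   `c("simulate", "select-markers", "quantify", "features", "search",
#'   "score", "evaluate")`.
#' @param verbose log stage timings to stderr.
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(cfg, stages = .PIPELINE_STAGES, verbose = TRUE) {
    if (is.character(cfg) && length(cfg) == 1) cfg <- readPipelineConfig(cfg)
    stopifnot(inherits(cfg, "PipelineConfig"))
    if (length(stages) == 0) return(invisible(list()))
    stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
    stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    panel <- MarkerPanel()
    epsilon <- if (is.null(cfg$epsilon)) defaultEpsilon(cfg$volumes)
               else cfg$epsilon
    res <- list()
    say <- function(...) if (verbose) message(...)
    tic <- function(stage, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- force(expr)
        say(sprintf("[%s] %.1fs", stage, proc.time()[["elapsed"]] - t0))
        out
    }
    path <- function(f) file.path(cfg$outdir, f)
    need <- function(f, producer) {
        if (!file.exists(path(f)))
            stop("missing artifact '", f, "'; run stage '", producer,
                 "' first")
        path(f)
    }

    if ("simulate" %in% stages) res$simulate <- tic("simulate", {
        ccfg <- cohortPreset(cfg$preset, seed = cfg$seed)
        for (k in names(cfg$cohortConfig)) ccfg[[k]] <- cfg$cohortConfig[[k]]
        roster <- simulateRoster(ccfg)
        writeRoster(roster, path("roster.csv"))
        acfg <- do.call(arraySimConfig,
                        c(cfg$arrayConfig,
                          list(seed = cfg$seed)[!"seed" %in%
                                                names(cfg$arrayConfig)]))
        arr <- simulateArrayData(acfg)
        writeBetaMatrix(arr$experiment, path("beta.tsv"),
                        path("sample_sheet.csv"))
        data.table::fwrite(arr$manifest, path("array_manifest.csv"))
        drp <- simulateDroplets(roster, panel, ccfg, cfg$volumes)
        writeDropletCsv(drp$droplets, path("droplets.csv"))
        data.table::fwrite(drp$manifest, path("droplet_manifest.csv"))
        .writeMeta(cfg, "simulate", cfg$outdir,
                   list(n_samples = nrow(roster)))
        list(roster = roster, array = arr, droplets = drp)
    })

    if ("select-markers" %in% stages) res$selectMarkers <- tic("select-markers", {
        exp <- readBetaMatrix(need("beta.tsv", "simulate"),
                              need("sample_sheet.csv", "simulate"))
        means <- computeGroupMeans(exp)
        cand <- selectCandidates(means, experiment = exp)
        data.table::fwrite(candidateTable(cand), path("candidates.csv"))
        ## heat-map-ready beta submatrix of the selected loci
        sel <- SummarizedExperiment::assay(exp, "beta")[uniqueLoci(cand), ,
                                                        drop = FALSE]
        data.table::fwrite(
            data.table::data.table(probe_id = rownames(sel), sel),
            path("candidate_beta_matrix.tsv"), sep = "\t")
        .writeMeta(cfg, "select-markers", cfg$outdir,
                   list(n_unique_loci = length(uniqueLoci(cand))))
        cand
    })

    if ("quantify" %in% stages) res$quantify <- tic("quantify", {
        roster <- readRoster(need("roster.csv", "simulate"))
        droplets <- readDropletCsv(need("droplets.csv", "simulate"),
                                   cfg$volumes)
        tf <- cfg$trainFraction
        if (is.null(tf))
            tf <- if (cfg$preset == "table1_cohort") table1SplitFractions()
                  else 0.6
        roster <- stratifiedSplit(roster, tf, seed = cfg$seed)
        writeRoster(roster, path("roster.csv"))
        trainIds <- roster$sample_id[roster$split == "train"]
        labels <- setNames(roster$class, roster$sample_id)
        dt <- dropletTable(droplets)
        trainDrop <- DropletData(dt[dt$sample_id %in% trainIds, ],
                                 dropletVolumes(droplets))
        st <- trainQuantification(trainDrop, labels[trainIds], panel,
                                  nGrid = cfg$nGrid)
        quants <- quantifyMarkers(droplets, st$thresholds, st$cutoffs,
                                  continuityCorrection = TRUE)
        data.table::fwrite(quants, path("marker_quants.csv"))
        writeModelState(list(panel = panel, thresholds = st$thresholds,
                             cutoffs = st$cutoffs, epsilon = epsilon,
                             volumes = cfg$volumes),
                        path("model_state.json"))
        .writeMeta(cfg, "quantify", cfg$outdir)
        quants
    })

    if ("features" %in% stages) res$features <- tic("features", {
        quants <- as.data.frame(
            data.table::fread(need("marker_quants.csv", "quantify")))
        feats <- buildFeatureTable(quants, panel, epsilon)
        data.table::fwrite(feats, path("features.csv"))
        .writeMeta(cfg, "features", cfg$outdir)
        feats
    })

    if ("search" %in% stages) res$search <- tic("search", {
        feats <- as.data.frame(
            data.table::fread(need("features.csv", "features")))
        roster <- readRoster(need("roster.csv", "simulate"))
        roster <- roster[match(feats$sample_id, roster$sample_id), ]
        tr <- roster$split == "train"
        sr <- exhaustiveSearch(feats[tr, ], roster$class[tr],
                               variables = cfg$searchVariables,
                               cost = cfg$cParam)
        data.table::fwrite(searchTable(sr), path("search_table.csv"))
        state <- readModelState(path("model_state.json"))
        state$model <- bestModel(sr)
        writeModelState(state, path("model_state.json"))
        .writeMeta(cfg, "search", cfg$outdir,
                   list(best_loocv_auc = sr@bestLoocvAUC,
                        constraint_satisfied = sr@constraintSatisfied))
        sr
    })

    if ("score" %in% stages) res$score <- tic("score", {
        feats <- as.data.frame(
            data.table::fread(need("features.csv", "features")))
        model <- if (cfg$useFixedModel) fixedPublishedModel()
        else {
            state <- readModelState(need("model_state.json", "search"))
            if (is.null(state$model))
                stop("model state has no model; run stage 'search' first ",
                     "or set useFixedModel")
            state$model
        }
        idx <- detectionIndex(model, feats)
        scored <- data.frame(sample_id = feats$sample_id,
                             detection_index = idx,
                             call = classifyIndex(idx, decisionCutoff(model)))
        data.table::fwrite(scored, path("scores.csv"))
        .writeMeta(cfg, "score", cfg$outdir)
        scored
    })

    if ("evaluate" %in% stages) res$evaluate <- tic("evaluate", {
        scored <- as.data.frame(
            data.table::fread(need("scores.csv", "score")))
        roster <- readRoster(need("roster.csv", "simulate"))
        roster <- roster[match(scored$sample_id, roster$sample_id), ]
        model <- if (cfg$useFixedModel) fixedPublishedModel()
                 else readModelState(need("model_state.json", "quantify"))$model
        cutoff <- if (is.null(model)) -0.07923 else decisionCutoff(model)
        reports <- lapply(c(train = "train", validation = "validation"),
                          function(sp) {
            sel <- roster$split == sp
            if (sum(sel) == 0) return(NULL)
            evaluationReport(scored$detection_index[sel], roster[sel, ],
                             cutoff)
        })
        jsonlite::write_json(reports, path("evaluation.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        rocs <- do.call(rbind, lapply(
            c("train", "validation"), function(sp) {
                sel <- roster$split == sp
                if (sum(sel) == 0) return(NULL)
                cbind(split = sp,
                      rocPoints(scored$detection_index[sel],
                                roster$class[sel]))
            }))
        data.table::fwrite(rocs, path("roc_points.csv"))
        .writeMeta(cfg, "evaluate", cfg$outdir)
        reports
    })

    invisible(res)
}
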