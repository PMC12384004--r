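# End-to-end orchestration: YAML config, staged execution with
# serialized intermediates, logging, and a Markdown report; plus the
# command-line entry point.

#' Build a pipeline configuration
#'
#' @param synthetic named list of \code{\link{cohortConfig}} arguments
#'   (synthetic input source), or \code{NULL}.
#' @param paths list with element \code{directory} pointing at a cohort
#'   written by \code{\link{writeCohort}}, or \code{NULL}. Exactly one
#'   of \code{synthetic} / \code{paths} must be given.
#' @param seed mandatory integer seed for every stochastic stage.
#' @param outdir output directory.
#' @param preprocessing,filters,selection,modeling,output stage options;
#'   see the default values in the function body.
#' @return A validated pipeline configuration list.
#' @export
pipelineConfig <- function(synthetic = NULL, paths = NULL, seed = NULL,
                           outdir = "dlco-radiomics-out",
                           preprocessing = list(), filters = list(),
                           selection = list(), modeling = list(),
                           output = list()) {
    cfg <- list(
        input = list(synthetic = synthetic, paths = paths),
        seed = seed, outdir = outdir,
        preprocessing = utils::modifyList(
            list(normalize = TRUE,
                 anchors = c(1, 5, 25, 50, 75, 95, 99),
                 bin_width_hu = 25, gtv_margin_mm = 0.5),
            preprocessing),
        filters = utils::modifyList(
            list(enabled = c("original", "wavelet", "log", "gradient",
                             "square", "squareroot", "logarithm",
                             "exponential"),
                 log_sigmas_mm = c(2, 4), wavelet_family = "coif1"),
            filters),
        selection = utils::modifyList(
            list(prune_rho = 0.95, cluster_rho = 0.75), selection),
        modeling = utils::modifyList(
            list(k = 3, reps = 100, clinical_covariates = "cci"),
            modeling),
        output = utils::modifyList(list(write_images = FALSE), output))
    validatePipelineConfig(cfg)
    cfg
}

#' Validate a pipeline configuration
#'
#' Field-by-field checks: exactly one input source, a mandatory integer
#' seed, positive numeric stage options.
#'
#' @param cfg a configuration list (e.g. from
#'   \code{\link{readPipelineConfig}}).
#' @return \code{cfg}, invisibly; stops with an informative message on
#'   the first violated constraint.
#' @export
validatePipelineConfig <- function(cfg) {
    hasSyn <- !is.null(cfg$input$synthetic)
    hasPaths <- !is.null(cfg$input$paths)
    if (hasSyn == hasPaths)
        stop("exactly one input source (synthetic XOR paths) is required")
    if (is.null(cfg$seed) || length(cfg$seed) != 1 ||
        is.na(suppressWarnings(as.integer(cfg$seed))))
        stop("an integer seed is mandatory")
    if (is.null(cfg$outdir) || !nzchar(cfg$outdir))
        stop("outdir is required")
    if (cfg$preprocessing$bin_width_hu <= 0)
        stop("bin_width_hu must be positive")
    if (cfg$modeling$k < 2) stop("k must be at least 2")
    if (cfg$modeling$reps < 1) stop("reps must be at least 1")
    if (hasPaths && is.null(cfg$input$paths$directory))
        stop("paths input needs a 'directory' field")
    invisible(cfg)
}

#' Read and validate a YAML pipeline configuration
#'
#' @param path YAML file.
#' @return The validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    pipelineConfig(synthetic = raw$input$synthetic,
                   paths = raw$input$paths, seed = raw$seed,
                   outdir = if (is.null(raw$outdir)) "dlco-radiomics-out"
                            else raw$outdir,
                   preprocessing = if (is.null(raw$preprocessing)) list()
                                   else raw$preprocessing,
                   filters = if (is.null(raw$filters)) list()
                             else raw$filters,
                   selection = if (is.null(raw$selection)) list()
                               else raw$selection,
                   modeling = if (is.null(raw$modeling)) list()
                              else raw$modeling,
                   output = if (is.null(raw$output)) list()
                            else raw$output)
}

pipelineLogger <- function(outdir) {
    logFile <- file.path(outdir, "log.txt")
    function(...) {
        line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
        cat(line, "\n", file = logFile, append = TRUE, sep = "")
        message(line)
    }
}

extractionConfigFrom <- function(cfg, normalizationMap = NULL) {
    en <- cfg$filters$enabled
    reg <- filterRegistry(
        original = "original" %in% en, wavelet = "wavelet" %in% en,
        log = "log" %in% en, gradient = "gradient" %in% en,
        square = "square" %in% en, squareroot = "squareroot" %in% en,
        logarithm = "logarithm" %in% en,
        exponential = "exponential" %in% en,
        logSigmasMm = cfg$filters$log_sigmas_mm,
        waveletFamily = cfg$filters$wavelet_family)
    extractionConfig(filters = reg,
                     binWidthHu = cfg$preprocessing$bin_width_hu,
                     gtvMarginMm = cfg$preprocessing$gtv_margin_mm,
                     normalizationMap = normalizationMap)
}

#' Run the full pipeline
#'
#' Executes, in order: simulate or load the cohort; fit the reference
#' histogram and preprocess; extract Phase 0, Phase 50 and delta
#' feature tables; run the screening and correlation-clustering
#' selection and fit the full-data LASSO score per phase design;
#' evaluate the thirteen models by repeated stratified k-fold
#' cross-validation; and write a Markdown report. Every intermediate is
#' serialized under \code{cfg$outdir} (clinical and feature CSVs,
#' selection and model JSONs, log with config hash), so later stages
#' can be resumed from disk, and reruns under the same configuration
#' are byte-identical in \code{results.json}.
#'
#' @param cfg a validated pipeline configuration.
#' @param startAt first stage to execute: \code{"simulate"} (default,
#'   full run) or \code{"select"}, which skips simulation and
#'   extraction by loading the clinical and feature CSVs already
#'   serialized under \code{cfg$outdir}.
#' @return Invisibly, a list with the cohort, feature tables, selection
#'   results, score models, model evaluation and the report path.
#' @export
runPipeline <- function(cfg, startAt = c("simulate", "select")) {
    startAt <- match.arg(startAt)
    validatePipelineConfig(cfg)
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    log <- pipelineLogger(cfg$outdir)
    cfgHash <- rlang::hash(cfg)
    log("pipeline start; config hash ", cfgHash, "; seed ", cfg$seed)
    withStage <- function(stage, expr)
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))

    cohort <- NULL
    if (startAt == "simulate") {
        cohort <- withStage("simulate/load", {
            if (!is.null(cfg$input$synthetic)) {
                args <- cfg$input$synthetic
                args$seed <- cfg$seed
                cc <- do.call(cohortConfig, args)
                generateCohort(cc)
            } else readCohort(cfg$input$paths$directory)
        })
        log("cohort ready: ", length(cohort@patients), " patients")
        if (length(cohort@patients) == 0) stop("empty cohort")
        write.csv(cohort@clinical, file.path(cfg$outdir, "clinical.csv"),
                  row.names = FALSE, na = "")
        if (isTRUE(cfg$output$write_images))
            writeCohort(cohort, file.path(cfg$outdir, "cohort"))

        extCfg <- withStage("preprocess", {
            nm <- NULL
            if (isTRUE(cfg$preprocessing$normalize)) {
                ref <- cohort@patients[[1]]@phase0
                nm <- fitReferenceHistogram(
                    ref, anchors = cfg$preprocessing$anchors)
            }
            extractionConfigFrom(cfg, nm)
        })

        feats <- withStage("extract", {
            t0 <- extractCohortFeatures(cohort, "phase0", extCfg)
            t50 <- extractCohortFeatures(cohort, "phase50", extCfg)
            list(Phase0 = t0, Phase50 = t50,
                 Delta = deltaFeatures(t0, t50))
        })
        for (nm in names(feats))
            writeFeatureTable(feats[[nm]],
                              file.path(cfg$outdir,
                                        paste0("features_", tolower(nm),
                                               ".csv")), extCfg)
        log("features extracted: ", ncol(featureMatrix(feats$Phase0)),
            " per phase")
        clinical <- cohort@clinical
    } else {
        feats <- withStage("load intermediates", {
            lapply(c(Phase0 = "phase0", Phase50 = "phase50",
                     Delta = "delta"),
                   function(nm) readFeatureTable(
                       file.path(cfg$outdir,
                                 paste0("features_", nm, ".csv"))))
        })
        clinical <- read.csv(file.path(cfg$outdir, "clinical.csv"),
                             stringsAsFactors = FALSE)
        if (!"dlco_post_pct" %in% names(clinical))
            clinical$dlco_post_pct <- NA_real_
        log("resumed from serialized features: ",
            ncol(featureMatrix(feats$Phase0)), " per phase")
    }

    data <- list(features = lapply(feats, featureMatrix),
                 clinical = clinical,
                 baselineLabel =
                     classifyDlco(clinical$dlco_baseline_pct) ==
                     "abnormal",
                 postLabel = local({
                     p <- rep(NA, nrow(clinical))
                     h <- !is.na(clinical$dlco_post_pct)
                     p[h] <- classifyDlco(
                         clinical$dlco_post_pct[h]) == "abnormal"
                     p
                 }))

    selCfg <- selectionConfig(pruneRho = cfg$selection$prune_rho,
                              clusterRho = cfg$selection$cluster_rho)
    selections <- withStage("select", {
        out <- list()
        for (design in names(data$features)) {
            res <- selectFeatures(data$features[[design]],
                                  data$baselineLabel, selCfg)
            writeSelectionResult(res, file.path(
                cfg$outdir, paste0("selection_", tolower(design),
                                   ".json")))
            log("selection ", design, ": ",
                paste(unlist(res@audit$screening), collapse = " -> "),
                " -> ", length(res@selected), " selected")
            out[[design]] <- res
        }
        out
    })

    scores <- withStage("score", {
        out <- list()
        for (design in names(selections)) {
            sel <- selections[[design]]@selected
            X <- data$features[[design]][, sel, drop = FALSE]
            Z <- scale(X)
            Z[, apply(X, 2, sd) == 0] <- 0
            out[[design]] <- fitLassoLogistic(Z, data$baselineLabel,
                                              seed = subSeed(cfg$seed,
                                                             match(design,
                                                                   names(selections))))
        }
        out
    })

    evalRes <- withStage("model", {
        evaluateModels(data, k = cfg$modeling$k, reps = cfg$modeling$reps,
                       seed = cfg$seed, selectionCfg = selCfg,
                       clinicalCovariates =
                           cfg$modeling$clinical_covariates)
    })
    write.csv(evalRes$summary,
              file.path(cfg$outdir, "model_aucs.csv"),
              row.names = FALSE)
    log("evaluated ", nrow(evalRes$summary), " models")

    assoc <- withStage("report", clinicalAssociationTable(
        clinical, data$baselineLabel,
        variables = c("cci", "copd", "smoking", "age")))
    hasPost <- !is.na(clinical$dlco_post_pct)
    postDrop <- if (sum(hasPost) >= 1)
        pairedWilcoxonSignedRank(clinical$dlco_baseline_pct[hasPost],
                                 clinical$dlco_post_pct[hasPost])
    else NA_real_

    resultJson <- list(
        config_hash = cfgHash, seed = cfg$seed,
        n_patients = nrow(clinical),
        dlco_reduction_signed_rank_p = postDrop,
        selected_features = lapply(selections,
                                   function(s) s@selected),
        score_models = lapply(scores, function(s)
            list(features = s@featureNames,
                 coefficients = s@coefficients)),
        clinical_associations = assoc,
        model_aucs = evalRes$summary)
    jsonlite::write_json(resultJson,
                         file.path(cfg$outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    reportPath <- writeReport(cfg, cfgHash, assoc, selections, scores,
                              evalRes, postDrop)
    log("pipeline done")
    invisible(list(cohort = cohort, features = feats,
                   selections = selections, scores = scores,
                   evaluation = evalRes, associations = assoc,
                   report = reportPath))
}

writeReport <- function(cfg, cfgHash, assoc, selections, scores,
                        evalRes, postDrop = NA_real_) {
    path <- file.path(cfg$outdir, "report.md")
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) cat(..., "\n", sep = "", file = con)
    w("# DLCO radiomics pipeline report")
    w("")
    w("Config hash: `", cfgHash, "`; seed: ", cfg$seed)
    w("")
    w("## Clinical associations with abnormal baseline DLCO")
    w("")
    w("| Variable | Test | p |")
    w("|---|---|---|")
    for (i in seq_len(nrow(assoc)))
        w("| ", assoc$variable[i], " | ", assoc$test[i], " | ",
          signif(assoc$p[i], 3), " |")
    w("")
    if (!is.na(postDrop)) {
        w("Baseline vs post-treatment DLCO (paired Wilcoxon ",
          "signed-rank, patients with both): p = ", signif(postDrop, 3))
        w("")
    }
    w("## Selected features and radiomic-score coefficients")
    w("")
    for (design in names(scores)) {
        s <- scores[[design]]
        w("### ", design)
        w("")
        w("| Feature | Coefficient |")
        w("|---|---|")
        for (j in seq_along(s@featureNames))
            w("| ", s@featureNames[j], " | ",
              signif(s@coefficients[j], 4), " |")
        w("")
    }
    w("## Repeated cross-validated AUC (median, IQR) of the 13 models")
    w("")
    w("| Kind | Phase design | Endpoint | Median AUC | IQR |")
    w("|---|---|---|---|---|")
    sm <- evalRes$summary
    for (i in seq_len(nrow(sm)))
        w("| ", sm$kind[i], " | ", sm$phaseDesign[i], " | ",
          sm$endpoint[i], " | ", sprintf("%.3f", sm$medianAUC[i]),
          " | ", sprintf("%.3f-%.3f", sm$q1[i], sm$q3[i]), " |")
    path
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (generate and write a cohort),
#' \code{extract}, \code{select}, \code{model}, \code{report} (resume
#' individual stages from the output directory) and \code{run} (full
#' pipeline). Flags: \code{--config <yaml>}, \code{--seed <int>},
#' \code{--outdir <dir>} (the latter two override the config file).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 1 on a stage failure, 2 on
#'   a usage error.
#' @export
pipelineCli <- function(args = commandArgs(trailingOnly = TRUE)) {
    usage <- function() {
        message("usage: dlco-radiomics <simulate|extract|select|model|",
                "report|run> --config <yaml> [--seed <int>] ",
                "[--outdir <dir>]")
        2L
    }
    if (length(args) < 1) return(usage())
    cmd <- args[1]
    if (!cmd %in% c("simulate", "extract", "select", "model", "report",
                    "run"))
        return(usage())
    args <- args[-1]
    opts <- list()
    i <- 1
    while (i <= length(args)) {
        key <- args[i]
        if (!key %in% c("--config", "--seed", "--outdir") ||
            i == length(args))
            return(usage())
        opts[[sub("^--", "", key)]] <- args[i + 1]
        i <- i + 2
    }
    if (is.null(opts$config)) return(usage())
    cfg <- tryCatch(readPipelineConfig(opts$config), error = function(e) {
        message("config error: ", conditionMessage(e))
        NULL
    })
    if (is.null(cfg)) return(2L)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$outdir)) cfg$outdir <- opts$outdir
    run <- function(expr) tryCatch({ expr; 0L }, error = function(e) {
        message("error: ", conditionMessage(e))
        1L
    })
    if (cmd == "run") return(run(runPipeline(cfg)))
    if (cmd == "simulate") return(run({
        if (is.null(cfg$input$synthetic))
            stop("simulate needs a synthetic input source")
        args2 <- cfg$input$synthetic
        args2$seed <- cfg$seed
        cohort <- generateCohort(do.call(cohortConfig, args2))
        writeCohort(cohort, file.path(cfg$outdir, "cohort"))
    }))
    if (cmd == "extract") return(run({
        cohortDir <- file.path(cfg$outdir, "cohort")
        if (dir.exists(cohortDir)) {
            cfg$input$synthetic <- NULL
            cfg$input$paths <- list(directory = cohortDir)
        }
        runPipeline(cfg)
    }))
    # select / model / report resume from the serialized feature CSVs
    if (cmd %in% c("select", "model", "report"))
        return(run(runPipeline(cfg, startAt = "select")))
    usage()
}
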