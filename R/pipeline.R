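#' Default pipeline configuration
#'
#' A nested settings list (YAML-serialisable) covering every stage. Exactly
#' one input mode is used: `simulate` (synthetic cohort), `feature_table`
#' (CSV of an extracted table) or `volumes` (NIfTI volumes + masks per VOI
#' per month). Every effective value is echoed into the run manifest.
#'
#' @param inputMode `"simulate"`, `"feature_table"` or `"volumes"`.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @return named configuration list.
#' @export
pipelineConfig <- function(inputMode = "simulate", seed = 1L) {
  list(
    inputMode = inputMode,
    seed = as.integer(seed),
    cohort = list(nPatients = 21L, nOrnVois = 22L, nControlVois = 21L,
                  nFeatures = 16L, signalMode = "shape", effectSize = 1.5,
                  noiseSd = 0.2, obsMonths = c(0, 2, 6),
                  withinPatientRho = 0.5, netChangeSd = 0.5),
    featureTablePath = NULL,
    volumes = NULL,
    extraction = list(targetSpacing = c(1, 1, 3), nLevels = 32L,
                      modes = c("3D", "2.5D"), nidNeighborhoods = c(3L, 5L, 7L)),
    screening = list(threshold = 0.5),
    kinetics = list(grid = 0:6, uPve = 0.99, mPve = 0.9, M = NULL),
    models = list(nTrees = 500L, nRepeats = 200L, testFraction = 1 / 3,
                  grouped = TRUE),
    evaluation = list(ciMethod = "delong")
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipelineConfig()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipelineConfig()
  merge2 <- function(base, user, prefix = "") {
    bad <- setdiff(names(user), names(base))
    if (length(bad)) stop("unknown config key(s): ",
                          paste0(prefix, bad, collapse = ", "))
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
        merge2(base[[k]], user[[k]], paste0(prefix, k, ".")) else user[[k]]
    }
    base
  }
  merge2(base, user)
}

#' Simulate a cohort and write its files
#'
#' Writes the trajectory table as CSV (long by time point, wide by
#' feature) and the ground truth as JSON next to it.
#'
#' @param config from [pipelineConfig()].
#' @param outDir output directory.
#' @param seed overrides `config$seed`.
#' @return invisibly, list with `csv`, `truth` paths and the cohort.
#' @export
simulateCohortFiles <- function(config = pipelineConfig(), outDir,
                                seed = config$seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  args <- config$cohort
  args$seed <- deriveSeed(seed, "simulate")
  spec <- do.call(cohortSpec, args)
  cohort <- generateTrajectoryCohort(spec)
  csv <- file.path(outDir, "cohort.csv")
  truthPath <- file.path(outDir, "cohort_truth.json")
  writeTrajectoryTable(cohort$table, csv)
  jsonlite::write_json(cohort$truth, truthPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(csv = csv, truth = truthPath, cohort = cohort))
}

# Resolve the pipeline's input table per the configured mode.
resolveInput <- function(config, outDir, seed) {
  switch(config$inputMode,
    simulate = {
      sim <- simulateCohortFiles(config, outDir, seed)
      list(table = sim$cohort$table, source = sim$csv)
    },
    feature_table = {
      if (is.null(config$featureTablePath)) stop("featureTablePath not set")
      list(table = readTrajectoryTable(config$featureTablePath),
           source = config$featureTablePath)
    },
    volumes = {
      if (is.null(config$volumes)) stop("volumes input not set")
      vois <- lapply(config$volumes, function(v) {
        months <- lapply(v$months, function(mm) {
          io <- readVolumeNifti(mm$volume, mm$mask)
          list(volume = io$volume, mask = io$masks[[1L]])
        })
        list(voi_id = v$voi_id, patient_id = v$patient_id, label = v$label,
             months = months)
      })
      cfg <- do.call(extractionConfig, config$extraction)
      list(table = extractFeatureTable(vois, cfg), source = "volumes")
    },
    stop("unknown inputMode: ", config$inputMode))
}

#' Run the end-to-end pipeline
#'
#' Resolves the input table, runs screening, kinetics, the five-model
#' suite and the evaluation stage, and writes the report bundle: the
#' cohort files (simulate mode), screening results, per-model predictions
#' and ROC points, the cross-model comparison table, a JSON report and a
#' reproducible run manifest (settings, derived seeds, input hash). Fully
#' deterministic given the seed.
#'
#' @param config from [pipelineConfig()] / [readPipelineConfig()].
#' @param outDir output directory.
#' @param seed overrides `config$seed`.
#' @return invisibly, list with the suite, the comparison table and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        seed = config$seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  input <- resolveInput(config, outDir, seed)
  spec <- modelSpec(nTrees = config$models$nTrees,
                    nRepeats = config$models$nRepeats,
                    testFraction = config$models$testFraction,
                    grouped = config$models$grouped,
                    seed = deriveSeed(seed, "models"))
  suite <- runModelSuite(input$table,
                         corrThreshold = config$screening$threshold,
                         grid = config$kinetics$grid,
                         uPve = config$kinetics$uPve,
                         mPve = config$kinetics$mPve,
                         M = config$kinetics$M, spec = spec)

  utils::write.csv(suite$screening$screening,
                   file.path(outDir, "screening.csv"), row.names = FALSE)
  writeLines(suite$screening$retained, file.path(outDir, "retained_features.txt"))

  predLong <- do.call(rbind, lapply(suite$predictions, function(p)
    cbind(p@data[, c("voi_id", "patient_id", "label", "prob_control",
                     "n_heldout")], representation = p@representation)))
  rownames(predLong) <- NULL
  utils::write.csv(predLong, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)

  evalSeed <- deriveSeed(seed, "evaluation")
  report <- list()
  for (nm in names(suite$predictions)) {
    ev <- evaluatePredictions(suite$predictions[[nm]],
                              ciMethod = config$evaluation$ciMethod,
                              seed = evalSeed)
    utils::write.csv(ev$roc@points,
                     file.path(outDir, sprintf("roc_%s.csv", nm)),
                     row.names = FALSE)
    report[[nm]] <- list(auc = ev$roc@auc, ci = ev$roc@ci,
                         ci_method = ev$roc@ciMethod, youden = ev$youden,
                         tau = ev$tau,
                         confusion = as.vector(ev$classification$confusion),
                         percent_correct = as.list(
                           ev$classification$percentCorrect))
  }
  cmp <- comparisonTable(suite, ciMethod = config$evaluation$ciMethod,
                         seed = evalSeed)
  utils::write.csv(cmp, file.path(outDir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "radkinetics",
    version = as.character(utils::packageVersion("radkinetics")),
    seed = seed,
    derived_seeds = list(simulate = deriveSeed(seed, "simulate"),
                         models = deriveSeed(seed, "models"),
                         evaluation = evalSeed),
    config = config[setdiff(names(config), c("volumes"))],
    input = list(mode = config$inputMode,
                 hash = if (file.exists(input$source))
                   unname(tools::md5sum(input$source)) else input$source),
    retained_features = suite$screening$retained,
    mfpca_components = suite$kinetics$mfpca@retained)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(suite = suite, comparison = cmp, manifest = manifest))
}
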