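#' @include synthetic.R featurize.R select.R experiment.R importance.R
NULL

#' Read and validate a pipeline configuration
#'
#' The single structured config file (YAML) governs every stage; all
#' randomness flows from the seeds named in it. \code{validateConfig} is
#' run before any computation and fails fast on structural problems —
#' notably a missing \code{selection.threshold}, which has no default at
#' the pipeline level so that the pruning cutoff is always an explicit,
#' recorded choice.
#'
#' @param path YAML file.
#' @param config configuration list.
#' @return \code{readConfig}: the validated configuration list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path))
    .validation_error(sprintf("config file not found: %s", path), field = "config")
  validateConfig(yaml::read_yaml(path))
}

#' @rdname readConfig
#' @export
validateConfig <- function(config) {
  if (is.null(config$input$type) ||
      !config$input$type %in% c("synthetic", "compounds"))
    .validation_error("input.type: must be 'synthetic' or 'compounds'",
                      field = "input.type")
  if (config$input$type == "compounds" && is.null(config$input$path))
    .validation_error("input.path: compounds input needs a file path",
                      field = "input.path")
  thr <- config$selection$threshold
  if (is.null(thr) || !is.numeric(thr) || length(thr) != 1L ||
      is.na(thr) || thr <= 0 || thr > 1)
    .validation_error("selection.threshold: required, a number in (0, 1]",
                      field = "selection.threshold")
  algs <- config$models$algorithms %||% .SUPPORTED_ALGORITHMS
  bad <- setdiff(algs, .SUPPORTED_ALGORITHMS)
  if (length(bad))
    .validation_error(sprintf("models.algorithms: unknown algorithm(s) %s",
                              paste(bad, collapse = ", ")),
                      field = "models.algorithms")
  config
}

#' Default pipeline configuration
#'
#' Synthetic input at the study-sized default spec, stub descriptor
#' backend, pruning threshold 0.95, the full algorithm suite at random
#' states 0/10/100, no LOOCV (enable per config), top-7 consensus report.
#'
#' @param seed master seed for the synthetic input.
#' @return Configuration list accepted by \code{\link{runAll}}.
#' @export
defaultConfig <- function(seed = 0L) {
  list(
    input = list(type = "synthetic", seed = as.integer(seed)),
    featurization = list(backend = "stub", radius = 2L, n_bits = 2048L),
    selection = list(threshold = 0.95),
    models = list(algorithms = .SUPPORTED_ALGORITHMS,
                  random_states = c(0L, 10L, 100L), loocv = FALSE,
                  hyperparameters = list()),
    importance = list(top_k = 7L)
  )
}

.spec_from_config <- function(input) {
  if (!is.null(input$n_samples) || !is.null(input$planted)) {
    blocks <- if (is.null(input$blocks))
      data.frame(size = integer(), rho = numeric())
    else do.call(rbind, lapply(input$blocks, as.data.frame))
    syntheticSpec(
      nSamples = input$n_samples %||% 74L,
      nDescriptors = input$n_descriptors %||% 60L,
      nFpBits = input$n_fp_bits %||% 2048L,
      blocks = blocks, fpDensity = input$fp_density %||% 0.05,
      planted = unlist(input$planted) %||% numeric(),
      noiseSd = input$noise_sd %||% 1,
      seed = input$seed %||% 0L)
  } else defaultSyntheticSpec(seed = input$seed %||% 0L)
}

.split_by_kind <- function(table) {
  kind <- featureKind(table)
  list(descriptors = .ft_keep_features(table, names(kind)[kind == "descriptor"]),
       fingerprints = .ft_keep_features(table,
                                        names(kind)[kind == "fingerprint_bit"]))
}

setMethod("show", "RunManifest", function(object) {
  cat(sprintf("RunManifest: %d outputs, seeds [%s]\n  %s\n",
              length(object@outputs),
              paste(object@seeds, collapse = ", "),
              paste(sprintf("%s: %s", names(object@outputs), object@outputs),
                    collapse = "\n  ")))
})

#' Run the whole pipeline end to end
#'
#' Executes featurize -> select -> train -> importance under one
#' configuration, writing every stage artifact (delimited text) plus a
#' provenance manifest (JSON) that records the config, seeds, software
#' versions and the md5 digest of every output file, enabling bit-identical
#' re-runs. Per-stage progress is logged to standard error and
#' \code{run.log}.
#'
#' @param config configuration list (see \code{\link{defaultConfig}}) or
#'   path to a YAML file.
#' @param outDir output directory, created if needed.
#' @return A \linkS4class{RunManifest}.
#' @examples
#' \donttest{
#' cfg <- defaultConfig(seed = 1)
#' cfg$input$n_fp_bits <- 64L  # keep the example light
#' cfg$models$algorithms <- c("lasso", "random_forest")
#' mf <- runAll(cfg, tempfile("run_"))
#' }
#' @export
runAll <- function(config, outDir) {
  if (is.character(config)) config <- readConfig(config)
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(outDir, "run.log"), open = "wt")
  on.exit(close(logfile))
  t0 <- Sys.time()
  outputs <- character()
  out <- function(tag, ...) {
    p <- file.path(outDir, ...)
    outputs[[tag]] <<- p
    p
  }

  ## stage 1: featurize (or generate)
  if (config$input$type == "synthetic") {
    spec <- .spec_from_config(config$input)
    ds <- generateDataset(spec)
    tables <- .split_by_kind(ds$table)
    y <- ds$y
    rejected <- data.frame()
    .log_stage("featurize", sprintf("synthetic: %d samples, %d features",
                                    ncol(ds$table), nrow(ds$table)),
               con = logfile)
  } else {
    backend <- descriptorBackend(config$featurization$backend %||% "stub",
                                 executable = config$featurization$executable %||% "")
    cmp <- readCompounds(config$input$path,
                         kRef = config$input$k_ref %||% NA_real_)
    ft <- buildFeatureTables(cmp$records, backend,
                             radius = config$featurization$radius %||% 2L,
                             nBits = config$featurization$n_bits %||% 2048L)
    tables <- list(descriptors = ft$descriptors, fingerprints = ft$fingerprints)
    y <- ft$y
    rejected <- rbind(
      if (nrow(cmp$rejected))
        data.frame(id = cmp$rejected$id, stage = "ingest",
                   reason = cmp$rejected$reason) else NULL,
      ft$rejected)
    .log_stage("featurize", sprintf("%d compounds in, %d featurized, %d rejected",
                                    length(cmp$records) + nrow(cmp$rejected),
                                    length(y), nrow(rejected)), con = logfile)
  }
  writeFeatureTable(tables$descriptors, out("descriptors", "descriptors.csv"))
  writeFeatureTable(tables$fingerprints, out("fingerprints", "fingerprints.csv"))
  utils::write.csv(data.frame(sample_id = names(y), y = unname(y)),
                   out("targets", "targets.csv"), row.names = FALSE)
  if (NROW(rejected))
    utils::write.csv(rejected, out("rejected", "rejected.csv"), row.names = FALSE)

  ## stage 2: select (descriptor table only; fingerprints stay complete)
  sel <- selectFeatures(tables$descriptors,
                        threshold = config$selection$threshold)
  writeSelectionReport(sel$report, out("selection", "selection_report.csv"))
  .log_stage("select", sprintf("%d -> %d descriptors (threshold %.3g)",
                               nrow(tables$descriptors),
                               length(keptFeatures(sel$report)),
                               config$selection$threshold), con = logfile)

  ## stage 3: train
  mcfg <- experimentConfig(
    algorithms = config$models$algorithms %||% .SUPPORTED_ALGORITHMS,
    randomStates = config$models$random_states %||% c(0L, 10L, 100L),
    nTest = config$models$n_test,
    loocv = isTRUE(config$models$loocv),
    hyperparameters = config$models$hyperparameters %||% list())
  runs <- runExperiment(sel$table, tables$fingerprints, y, mcfg)
  grid <- resultsGrid(runs)
  utils::write.csv(grid, out("grid", "accuracy_grid.csv"), row.names = FALSE)
  fails <- attr(runs, "failures")
  if (NROW(fails))
    utils::write.csv(fails, out("failures", "failed_cells.csv"),
                     row.names = FALSE)
  .log_stage("train", sprintf("%d runs, %d skipped/failed cells",
                              length(runs), NROW(fails)), con = logfile)

  ## stage 4: importance consensus
  for (fs in c("descriptor", "fingerprint", "combined")) {
    cons <- withCallingHandlers(
      buildConsensus(runs, featureSet = fs),
      warning = function(w) invokeRestart("muffleWarning"))
    writeConsensus(cons, out(paste0("consensus_", fs),
                             sprintf("consensus_%s.csv", fs)))
    if (fs == "combined") {
      top <- topFeatures(cons, k = config$importance$top_k %||% 7L)
      utils::write.csv(top, out("top_features", "top_features.csv"),
                       row.names = FALSE)
    }
  }
  .log_stage("importance", "consensus written (descriptor/fingerprint/combined)",
             con = logfile)

  digests <- tools::md5sum(outputs)
  names(digests) <- names(outputs)
  manifest <- methods::new("RunManifest", config = config,
                           seeds = as.integer(mcfg$randomStates),
                           outputs = outputs, digests = digests,
                           versions = c(
                             R = paste(R.version$major, R.version$minor, sep = "."),
                             soacqspr = as.character(utils::packageVersion("soacqspr"))),
                           timestamps = c(start = t0, end = Sys.time()))
  jsonlite::write_json(
    list(config = config, seeds = mcfg$randomStates,
         outputs = as.list(outputs), digests = as.list(digests),
         versions = as.list(manifest@versions),
         timestamps = as.list(format(manifest@timestamps))),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  manifest
}
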