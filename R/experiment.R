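#' @include models.R
NULL

#' Model identifier string
#'
#' @param run A \linkS4class{ModelRun}.
#' @return \code{"algorithm/featureSet/randomState"}.
#' @export
modelId <- function(run)
  sprintf("%s/%s/%d", run@algorithm, run@featureSet, run@randomState)

setMethod("show", "ModelRun", function(object) {
  cat(sprintf("ModelRun %s: r2 = %.3f, rmse = %.3f, rmse_loo = %s\n",
              modelId(object), object@r2, object@rmse,
              if (is.na(object@rmseLoo)) "NA" else sprintf("%.3f", object@rmseLoo)))
})

#' Default experiment configuration
#'
#' The evaluation protocol: every algorithm of the suite, both feature sets,
#' random states 0/10/100 for the 66/8-style split, LOOCV on the training
#' partition.
#'
#' @param algorithms algorithm names to run.
#' @param randomStates integer split/fit seeds.
#' @param nTest test-partition size; NULL means \code{\link{defaultTestSize}}.
#' @param loocv logical; compute the leave-one-out score on each training
#'   partition (n extra fits per run).
#' @param hyperparameters per-algorithm overrides of
#'   \code{\link{defaultHyperparameters}}.
#' @return Configuration list for \code{\link{runExperiment}}.
#' @export
experimentConfig <- function(algorithms = .SUPPORTED_ALGORITHMS,
                             randomStates = c(0L, 10L, 100L), nTest = NULL,
                             loocv = TRUE, hyperparameters = list()) {
  list(algorithms = algorithms, randomStates = as.integer(randomStates),
       nTest = nTest, loocv = loocv, hyperparameters = hyperparameters)
}

#' Run the full evaluation grid
#'
#' One \linkS4class{ModelRun} per (algorithm x feature set x random state):
#' split the data, fit on the training partition, score R^2/RMSE on the test
#' partition and (optionally) the leave-one-out score on the training
#' partition, and extract the model's feature-importance vector. Cells whose
#' algorithm backend is unavailable are skipped and logged; other per-cell
#' failures are recorded and the grid is still produced.
#'
#' @param descriptors,fingerprints \linkS4class{FeatureTable}s over the same
#'   samples (either may be NULL to run a single feature set).
#' @param y named target vector aligned to the tables.
#' @param config list from \code{\link{experimentConfig}}.
#' @return List of \linkS4class{ModelRun}s, with a data.frame of skipped /
#'   failed cells in attribute \code{"failures"}.
#' @export
runExperiment <- function(descriptors, fingerprints, y,
                          config = experimentConfig()) {
  sets <- list()
  if (!is.null(descriptors)) sets$descriptor <- descriptors
  if (!is.null(fingerprints)) sets$fingerprint <- fingerprints
  if (!length(sets))
    .validation_error("descriptors/fingerprints: at least one table required",
                      field = "tables")
  for (nm in names(sets))
    if (length(y) != ncol(sets[[nm]]))
      .validation_error(sprintf("y: length differs from '%s' table samples", nm),
                        field = "y")

  runs <- list()
  failures <- data.frame(algorithm = character(), featureSet = character(),
                         randomState = integer(), type = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (algorithm in config$algorithms) {
    for (set_name in names(sets)) {
      for (rs in config$randomStates) {
        run <- tryCatch(
          .run_cell(algorithm, set_name, sets[[set_name]], y, rs, config),
          soacqspr_capability_error = function(e)
            structure(conditionMessage(e), type = "skipped"),
          error = function(e)
            structure(conditionMessage(e), type = "failed"))
        if (is.character(run)) {
          failures[nrow(failures) + 1L, ] <-
            list(algorithm, set_name, rs, attr(run, "type"), as.character(run))
          message(sprintf("[grid] %s %s/%s/%d: %s", attr(run, "type"),
                          algorithm, set_name, rs, as.character(run)))
        } else {
          runs[[length(runs) + 1L]] <- run
        }
      }
    }
  }
  attr(runs, "failures") <- failures
  runs
}

.run_cell <- function(algorithm, set_name, table, y, rs, config) {
  nTest <- config$nTest %||% defaultTestSize(ncol(table))
  parts <- splitDataset(table, y, nTest = nTest, randomState = rs)
  ## partition invariants, asserted every run
  stopifnot(length(intersect(parts$train$ids, parts$test$ids)) == 0L,
            length(parts$train$ids) + length(parts$test$ids) == ncol(table))
  hp <- config$hyperparameters[[algorithm]] %||% list()
  fit <- fitModel(algorithm, parts$train$x, parts$train$y, hp,
                  randomState = rs, testX = parts$test$x)
  preds <- as.numeric(fit$predict(parts$test$x))
  metrics <- evaluateModel(preds, parts$test$y)
  rmse_loo <- if (isTRUE(config$loocv))
    as.numeric(loocv(algorithm, parts$train$x, parts$train$y, hp,
                     randomState = rs))
  else NA_real_
  importance <- fit$importance
  if (is.null(importance)) importance <- numeric()
  methods::new("ModelRun", algorithm = algorithm, featureSet = set_name,
               randomState = as.integer(rs),
               hyperparameters = fit$hyperparameters %||% hp,
               r2 = metrics$r2, rmse = metrics$rmse, rmseLoo = rmse_loo,
               importance = importance,
               predictions = stats::setNames(preds, parts$test$ids),
               trainIds = parts$train$ids, testIds = parts$test$ids)
}

#' Accuracy grid of an experiment
#'
#' The run list condensed to the accuracy-table shape: one row per
#' (algorithm x feature set x random state) with R^2, RMSE and RMSE_LOO,
#' plus per-(algorithm x feature set) means across random states.
#'
#' @param runs list of \linkS4class{ModelRun}s from
#'   \code{\link{runExperiment}}.
#' @param means logical; append mean rows (random_state = NA).
#' @return data.frame with columns algorithm, feature_set, random_state, r2,
#'   rmse, rmse_loo.
#' @export
resultsGrid <- function(runs, means = TRUE) {
  grid <- do.call(rbind, lapply(runs, function(r)
    data.frame(algorithm = r@algorithm, feature_set = r@featureSet,
               random_state = r@randomState, r2 = r@r2, rmse = r@rmse,
               rmse_loo = r@rmseLoo, stringsAsFactors = FALSE)))
  if (is.null(grid)) return(data.frame())
  grid <- grid[order(grid$algorithm, grid$feature_set, grid$random_state), ]
  rownames(grid) <- NULL
  if (means && nrow(grid)) {
    agg <- stats::aggregate(grid[c("r2", "rmse", "rmse_loo")],
                            by = grid[c("algorithm", "feature_set")],
                            FUN = function(v) mean(v))
    agg <- data.frame(agg[1:2], random_state = NA_integer_,
                      agg[c("r2", "rmse", "rmse_loo")])
    grid <- rbind(grid, agg)
  }
  grid
}
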