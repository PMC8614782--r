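#' @include AllClasses.R FeatureTable.R
NULL

.SUPPORTED_ALGORITHMS <- c("xgboost", "lightgbm", "catboost", "random_forest",
                           "adaboost", "lasso", "dnn")
.IMPORTANCE_ALGORITHMS <- setdiff(.SUPPORTED_ALGORITHMS, "dnn")

#' Default test-partition size
#'
#' 8 held-out samples when n = 74 (the protocol's 66/8 split); otherwise the
#' same fraction, \code{round(n * 8/74)}, floored at 1.
#'
#' @param nTotal number of samples.
#' @return Integer test-set size.
#' @export
defaultTestSize <- function(nTotal) {
  if (nTotal == 74L) 8L else max(1L, as.integer(round(nTotal * 8 / 74)))
}

#' Random train/test partition
#'
#' Disjoint, exhaustive partition into \code{nTotal - nTest} training and
#' \code{nTest} test samples, deterministic per \code{randomState}.
#'
#' @param nTotal total sample count.
#' @param nTest test-set size (default \code{\link{defaultTestSize}}).
#' @param randomState integer seed of the partition.
#' @return List with sorted integer index vectors \code{train} and
#'   \code{test}.
#' @examples
#' sp <- splitIndices(74, randomState = 0)
#' lengths(sp)  # 66 / 8
#' @export
splitIndices <- function(nTotal, nTest = defaultTestSize(nTotal),
                         randomState = 0L) {
  nTotal <- .assert_count(nTotal, "nTotal", min = 2L)
  nTest <- .assert_count(nTest, "nTest", min = 1L)
  if (nTest >= nTotal)
    .validation_error("nTest: must be smaller than nTotal", field = "nTest")
  test <- sort(.with_op_seed(randomState, "split", sample.int(nTotal, nTest)))
  list(train = setdiff(seq_len(nTotal), test), test = test)
}

#' @describeIn splitIndices Partition a feature table and target vector.
#' @param table A \linkS4class{FeatureTable}.
#' @param y target vector aligned to the table's samples.
#' @return \code{splitDataset}: list with \code{train} and \code{test}, each
#'   a list \code{(x, y, ids)}.
#' @export
splitDataset <- function(table, y, nTest = defaultTestSize(ncol(table)),
                         randomState = 0L) {
  x <- featureMatrix(table)
  if (length(y) != nrow(x))
    .validation_error("y: length must equal the number of samples", field = "y")
  idx <- splitIndices(nrow(x), nTest, randomState)
  part <- function(i) list(x = x[i, , drop = FALSE], y = unname(y[i]),
                           ids = rownames(x)[i])
  list(train = part(idx$train), test = part(idx$test))
}

#' Test-set metrics
#'
#' \code{r2 = 1 - SS_res/SS_tot} with \code{SS_tot} about the test-set mean
#' (may be negative, never clipped); \code{rmse = sqrt(mean((y - yhat)^2))}.
#' With constant test targets r2 is undefined and reported as NA with a
#' warning; rmse is still returned.
#'
#' @param predictions numeric predictions.
#' @param y observed targets, same length.
#' @return List with \code{r2} and \code{rmse}.
#' @examples
#' evaluateModel(c(0, 1, 1, 1), c(0, 0, 1, 1))  # rmse 0.5, r2 0
#' @export
evaluateModel <- function(predictions, y) {
  if (length(predictions) != length(y) || !length(y))
    .validation_error("predictions/y: non-empty vectors of equal length required",
                      field = "predictions")
  rmse <- sqrt(mean((y - predictions)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("test targets are constant; r2 undefined (NA)")
    return(list(r2 = NA_real_, rmse = rmse))
  }
  list(r2 = 1 - sum((y - predictions)^2) / ss_tot, rmse = rmse)
}

## -- algorithm adapters -----------------------------------------------------

#' Default hyperparameters per algorithm
#'
#' The defaults the suite ships (the original protocol's tuning is not
#' public); every \linkS4class{ModelRun} records the full set actually used.
#' Values target a 60-70 sample regression problem: shallow trees, modest
#' learning rates, leaf sizes small enough for n = 66.
#'
#' @return Named list: algorithm -> hyperparameter list.
#' @export
defaultHyperparameters <- function() {
  list(
    xgboost = list(nrounds = 300L, eta = 0.05, max_depth = 4L,
                   subsample = 0.9, colsample_bytree = 0.9),
    lightgbm = list(num_boost_round = 300L, learning_rate = 0.05,
                    num_leaves = 15L, min_data_in_leaf = 5L,
                    feature_fraction = 0.9),
    catboost = list(),
    random_forest = list(ntree = 500L, nodesize = 3L),
    adaboost = list(nEstimators = 50L, maxdepth = 3L),
    lasso = list(lambda = NULL, nfolds = 5L),
    dnn = list(hidden_layer_sizes = c(64L, 32L), alpha = 1e-3,
               max_iter = 2000L)
  )
}

.fit_lasso <- function(x, y, hp, randomState) {
  if (ncol(x) < 2L) x <- cbind(x, `..dummy` = 0)  # glmnet needs >= 2 columns
  lambda <- hp$lambda
  if (is.null(lambda)) {
    nfolds <- min(hp$nfolds %||% 5L, length(y))
    cv <- .with_op_seed(randomState, "lasso-cv",
                        glmnet::cv.glmnet(x, y, alpha = 1, nfolds = nfolds))
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda)
  beta <- as.numeric(stats::coef(fit))[-1]
  names(beta) <- colnames(x)
  beta <- beta[names(beta) != "..dummy"]
  list(predict = function(newx) {
         if (ncol(newx) < 2L) newx <- cbind(newx, `..dummy` = 0)
         drop(stats::predict(fit, newx))
       },
       importance = abs(beta),
       hyperparameters = utils::modifyList(hp, list(lambda = lambda)))
}

.fit_random_forest <- function(x, y, hp, randomState) {
  fit <- .with_op_seed(randomState, "rf",
    randomForest::randomForest(
      x = x, y = y, ntree = hp$ntree %||% 500L,
      mtry = hp$mtry %||% max(1L, floor(ncol(x) / 3)),
      nodesize = hp$nodesize %||% 3L))
  imp <- fit$importance[, "IncNodePurity"]
  names(imp) <- rownames(fit$importance)
  list(predict = function(newx) unname(stats::predict(fit, newx)),
       importance = pmax(imp, 0), hyperparameters = hp)
}

.fit_xgboost <- function(x, y, hp, randomState) {
  params <- list(objective = "reg:squarederror", eta = hp$eta %||% 0.05,
                 max_depth = hp$max_depth %||% 4L,
                 subsample = hp$subsample %||% 0.9,
                 colsample_bytree = hp$colsample_bytree %||% 0.9,
                 nthread = 1L, seed = randomState)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = hp$nrounds %||% 300L, verbose = 0)
  imp_tab <- xgboost::xgb.importance(model = fit)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  imp[imp_tab$Feature] <- imp_tab$Gain
  list(predict = function(newx)
         stats::predict(fit, xgboost::xgb.DMatrix(newx)),
       importance = imp, hyperparameters = hp)
}

.weighted_median <- function(values, weights) {
  o <- order(values)
  values <- values[o]; weights <- weights[o]
  cw <- cumsum(weights) / sum(weights)
  values[which(cw >= 0.5)[1]]
}

## AdaBoost.R2 (Drucker-style) over rpart regression trees: weighted
## resampling, linear loss, weighted-median prediction, log(1/beta) model
## weights. No installed package offers boosting for regression, so the
## meta-algorithm lives here; the base learner is rpart.
.fit_adaboost <- function(x, y, hp, randomState) {
  n <- length(y)
  n_est <- hp$nEstimators %||% 50L
  ctrl <- rpart::rpart.control(maxdepth = hp$maxdepth %||% 3L, cp = 0,
                               minsplit = hp$minsplit %||% 5L, xval = 0)
  df_all <- as.data.frame(x)
  models <- list(); betas <- numeric()
  .with_op_seed(randomState, "adaboost", {
    w <- rep(1 / n, n)
    for (t in seq_len(n_est)) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      df <- cbind(.y = y[idx], df_all[idx, , drop = FALSE])
      fit <- rpart::rpart(.y ~ ., data = df, control = ctrl)
      pred <- stats::predict(fit, df_all)
      err <- abs(pred - y)
      me <- max(err)
      if (me <= 0) {  # perfect fit: keep it with (near-)total weight
        models[[length(models) + 1L]] <- fit
        betas[length(betas) + 1L] <- 1e-10
        break
      }
      loss <- err / me
      lbar <- sum(w * loss)
      if (lbar >= 0.5) {
        if (!length(models)) { models[[1L]] <- fit; betas[1L] <- 0.5 }
        break
      }
      beta <- max(lbar / (1 - lbar), 1e-10)
      models[[length(models) + 1L]] <- fit
      betas[length(betas) + 1L] <- beta
      w <- w * beta^(1 - loss)
      w <- w / sum(w)
    }
  })
  mw <- log(1 / betas)
  imp <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (t in seq_along(models)) {
    vi <- models[[t]]$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + mw[t] * vi
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  list(predict = function(newx) {
         preds <- vapply(models, function(m) stats::predict(m, as.data.frame(newx)),
                         numeric(nrow(newx)))
         preds <- matrix(preds, nrow = nrow(newx))
         apply(preds, 1L, .weighted_median, weights = mw)
       },
       importance = imp,
       hyperparameters = utils::modifyList(hp, list(nIterationsUsed = length(models))))
}

## -- subprocess adapters (LightGBM, MLP) ------------------------------------
## LightGBM and the DNN baseline have no installed R implementation; both are
## delegated to library implementations driven through a small subprocess
## runner (CSV in, JSON out), seeded and single-threaded for determinism.

.soac_env <- new.env(parent = emptyenv())

.python_binary <- function() {
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  ""
}

.py_lib_available <- function(lib) {
  key <- paste0("pylib_", lib)
  if (!is.null(.soac_env[[key]])) return(.soac_env[[key]])
  py <- .python_binary()
  ok <- nzchar(py) &&
    system2(py, c("-c", shQuote(paste0("import ", lib))),
            stdout = FALSE, stderr = FALSE) == 0
  .soac_env[[key]] <- ok
  ok
}

.assert_py_backend <- function(algorithm) {
  lib <- switch(algorithm, lightgbm = "lightgbm", mlp = "sklearn")
  if (!.py_lib_available(lib))
    .capability_error(sprintf(
      "%s backend unavailable: no python interpreter with the %s package on PATH",
      algorithm, lib), backend = algorithm)
}

.py_script <- function() {
  s <- system.file("python", "py_backend.py", package = "soacqspr")
  if (!nzchar(s)) s <- file.path("inst", "python", "py_backend.py")
  s
}

.py_call <- function(job) {
  dir <- tempfile("pyjob_")
  dir.create(dir)
  job$out <- file.path(dir, "result.json")
  job_path <- file.path(dir, "job.json")
  jsonlite::write_json(job, job_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2(.python_binary(), c(.py_script(), job_path),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(job$out))
    stop(sprintf("%s backend call failed (exit %d)", job$algorithm, status))
  res <- jsonlite::read_json(job$out, simplifyVector = TRUE)
  unlink(dir, recursive = TRUE)
  res
}

.py_write_x <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  path
}

.fit_py_model <- function(algorithm, x, y, hp, randomState, test_x = NULL) {
  .assert_py_backend(algorithm)
  work <- tempfile(paste0(algorithm, "_model_"))
  dir.create(work)
  train_csv <- file.path(work, "train.csv")
  utils::write.csv(cbind(.y = y, as.data.frame(x)), train_csv, row.names = FALSE)
  job <- list(algorithm = algorithm, mode = "fit", train = train_csv,
              seed = randomState, params = hp)
  if (algorithm == "lightgbm") job$model <- file.path(work, "model.txt")
  cached <- NULL
  if (!is.null(test_x)) {
    job$test <- .py_write_x(test_x, file.path(work, "test.csv"))
    cached <- test_x
  }
  res <- .py_call(job)
  importance <- NULL
  if (!is.null(res$importance)) {
    importance <- stats::setNames(numeric(ncol(x)), colnames(x))
    importance[names(res$importance)] <- unlist(res$importance)
    importance <- pmax(importance, 0)
  }
  cached_pred <- res$predictions
  predict_fun <- function(newx) {
    if (!is.null(cached) && isTRUE(all.equal(unname(newx), unname(cached))))
      return(cached_pred)
    if (algorithm == "lightgbm") {
      nd <- .py_write_x(newx, tempfile(fileext = ".csv"))
      out <- .py_call(list(algorithm = algorithm, mode = "predict",
                           model = job$model, newdata = nd,
                           seed = randomState))
      unlink(nd)
      out$predictions
    } else {
      ## refit deterministically with newx as the prediction set
      refit <- utils::modifyList(job, list(test = .py_write_x(
        newx, tempfile(fileext = ".csv"))))
      refit$model <- NULL
      .py_call(refit)$predictions
    }
  }
  list(predict = predict_fun, importance = importance, hyperparameters = hp)
}

.py_loocv <- function(algorithm, x, y, hp, randomState) {
  .assert_py_backend(algorithm)
  train_csv <- tempfile(fileext = ".csv")
  utils::write.csv(cbind(.y = y, as.data.frame(x)), train_csv, row.names = FALSE)
  res <- .py_call(list(algorithm = algorithm, mode = "loocv",
                       train = train_csv, seed = randomState, params = hp))
  unlink(train_csv)
  as.numeric(res$loocv_abs_errors)
}

.fit_lightgbm <- function(x, y, hp, randomState, test_x = NULL)
  .fit_py_model("lightgbm", x, y, hp, randomState, test_x)

## Small fixed multilayer perceptron (standardized inputs), run out of
## process; optional baseline with no importance vector.
.fit_dnn <- function(x, y, hp, randomState, test_x = NULL)
  .fit_py_model("mlp", x, y, hp, randomState, test_x)

## -- fitModel / loocv -------------------------------------------------------

#' Fit one regression model
#'
#' Adapter over the suite's regression families. \code{algorithm} may also
#' be a function \code{(x, y, hyperparameters, randomState) -> list(predict,
#' importance)}, which is the extension seam used for custom or reference
#' predictors.
#'
#' @param algorithm one of \code{xgboost}, \code{lightgbm}, \code{catboost},
#'   \code{random_forest}, \code{adaboost}, \code{lasso}, \code{dnn}, or a
#'   fitter function.
#' @param x training matrix, samples x features, with column names.
#' @param y numeric targets.
#' @param hyperparameters algorithm-specific list; missing entries take the
#'   values of \code{\link{defaultHyperparameters}}.
#' @param randomState integer seed controlling all stochastic parts of the
#'   fit.
#' @param testX optional test matrix; adapters that can, precompute its
#'   predictions at fit time (used by the backends that run out of process).
#' @return List with \code{predict(newx)}, \code{importance} (named
#'   nonnegative numeric, or NULL for dnn) and \code{hyperparameters} (the
#'   full set used). An algorithm whose backing library is missing raises a
#'   capability error; an unknown name raises an error listing the supported
#'   algorithms.
#' @export
fitModel <- function(algorithm, x, y, hyperparameters = list(),
                     randomState = 0L, testX = NULL) {
  if (is.function(algorithm))
    return(algorithm(x, y, hyperparameters, randomState))
  if (!is.character(algorithm) || !algorithm %in% .SUPPORTED_ALGORITHMS)
    stop(sprintf("unknown algorithm '%s'; supported: %s",
                 as.character(algorithm)[1],
                 paste(.SUPPORTED_ALGORITHMS, collapse = ", ")))
  if (!nrow(x) || !length(y))
    .validation_error("x/y: training set must be non-empty", field = "x")
  hp <- utils::modifyList(defaultHyperparameters()[[algorithm]] %||% list(),
                          hyperparameters)
  fit <- switch(algorithm,
    lasso = .fit_lasso(x, y, hp, randomState),
    random_forest = .fit_random_forest(x, y, hp, randomState),
    xgboost = .fit_xgboost(x, y, hp, randomState),
    adaboost = .fit_adaboost(x, y, hp, randomState),
    dnn = .fit_dnn(x, y, hp, randomState, test_x = testX),
    lightgbm = .fit_lightgbm(x, y, hp, randomState, test_x = testX),
    catboost = .capability_error(
      "CatBoost backend unavailable: no installed implementation",
      backend = "catboost"))
  fit$algorithm <- algorithm
  fit
}

#' Leave-one-out cross-validation score
#'
#' n folds; fold i is trained on the other n-1 samples and evaluated on
#' sample i alone, so the per-fold RMSE is \code{|y_i - yhat_i|}. The score
#' is the mean over folds — i.e. the mean absolute leave-one-out error
#' (the direct consequence of averaging single-sample RMSEs).
#'
#' @inheritParams fitModel
#' @return \code{rmseLoo} (numeric scalar) with the per-fold absolute errors
#'   in attribute \code{"abs_errors"}.
#' @export
loocv <- function(algorithm, x, y, hyperparameters = list(), randomState = 0L) {
  n <- length(y)
  if (n < 3L) .validation_error("y: LOOCV needs n >= 3", field = "y")
  errs <- if (identical(algorithm, "lightgbm") || identical(algorithm, "dnn")) {
    hp <- utils::modifyList(defaultHyperparameters()[[algorithm]], hyperparameters)
    .py_loocv(switch(algorithm, lightgbm = "lightgbm", dnn = "mlp"),
              x, y, hp, randomState)
  } else {
    vapply(seq_len(n), function(i) {
      fit <- tryCatch(
        fitModel(algorithm, x[-i, , drop = FALSE], y[-i], hyperparameters,
                 randomState),
        error = function(e)
          stop(sprintf("LOOCV fold %d failed: %s", i, conditionMessage(e))))
      abs(y[i] - fit$predict(x[i, , drop = FALSE]))
    }, numeric(1))
  }
  structure(mean(errs), abs_errors = errs)
}
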