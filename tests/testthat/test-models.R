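test_that("the protocol split partitions 74 samples into 66/8", {
  sp <- splitIndices(74, randomState = 0)
  expect_length(sp$train, 66)
  expect_length(sp$test, 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:74)
  ## deterministic per random state
  expect_identical(sp, splitIndices(74, randomState = 0))
  ## the three protocol random states give distinct partitions
  parts <- lapply(c(0, 10, 100), function(rs) splitIndices(74, randomState = rs)$test)
  expect_false(identical(parts[[1]], parts[[2]]))
  expect_false(identical(parts[[1]], parts[[3]]))
  ## scaled default for other n
  expect_equal(defaultTestSize(74), 8)
  expect_equal(defaultTestSize(37), 4)
  expect_error(splitIndices(10, nTest = 10), "nTest")
})

test_that("test metrics match hand-computed values", {
  expect_equal(evaluateModel(c(1, 2, 3), c(1, 2, 3)), list(r2 = 1, rmse = 0))
  y <- c(0, 0, 1, 1)
  ## predicting the test mean gives r2 = 0
  expect_equal(evaluateModel(rep(mean(y), 4), y)$r2, 0)
  ## SS_res = 1, SS_tot = 1 -> r2 = 0, rmse = 0.5
  m <- evaluateModel(c(0, 1, 1, 1), y)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$r2, 0)
  ## worse-than-mean predictions go negative, not clipped
  expect_lt(evaluateModel(c(5, 5, 5, 5), y)$r2, 0)
  ## constant targets: r2 NA with warning, rmse still defined
  expect_warning(m2 <- evaluateModel(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(m2$r2))
  expect_equal(m2$rmse, sqrt(mean(c(4, 1))))
})

test_that("lasso recovers a noiseless single-feature linear signal", {
  set.seed(10)
  x <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "f1"))
  y <- 3 * x[, 1]
  fit <- fitModel("lasso", x[1:60, , drop = FALSE], y[1:60],
                  list(lambda = 1e-4))
  m <- evaluateModel(fit$predict(x[61:80, , drop = FALSE]), y[61:80])
  expect_gt(m$r2, 0.99)
  expect_equal(unname(fit$importance["f1"]), 3, tolerance = 0.05)
})

test_that("random forest on constant targets predicts that constant", {
  set.seed(11)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fit <- suppressWarnings(
    fitModel("random_forest", x, rep(2.5, 20), list(ntree = 50L)))
  expect_equal(unname(fit$predict(x)), rep(2.5, 20))
})

test_that("tree-ensemble importance vectors align with the feature set", {
  set.seed(12)
  x <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * x[, 2] + rnorm(40, sd = 0.2)
  for (alg in intersect(c("random_forest", "xgboost", "adaboost", "lightgbm"),
                        available_algorithms())) {
    fit <- fitModel(alg, x, y, fast_hp()[[alg]] %||% list(), randomState = 1)
    expect_length(fit$importance, 5)
    expect_named(fit$importance, paste0("f", 1:5))
    expect_true(all(fit$importance >= 0), info = alg)
    expect_equal(names(which.max(fit$importance)), "f2", info = alg)
  }
})

test_that("unknown and unavailable algorithms fail as contracted", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fitModel("boosted_llama", x, rnorm(10)), "supported")
  expect_error(fitModel("catboost", x, rnorm(10)),
               class = "soacqspr_capability_error")
})

test_that("model fits are deterministic per random state", {
  set.seed(13)
  x <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1] - x[, 4] + rnorm(50, sd = 0.3)
  newx <- x[1:5, , drop = FALSE]
  for (alg in available_algorithms()) {
    f1 <- fitModel(alg, x, y, fast_hp()[[alg]] %||% list(), randomState = 7)
    f2 <- fitModel(alg, x, y, fast_hp()[[alg]] %||% list(), randomState = 7)
    expect_equal(f1$predict(newx), f2$predict(newx), info = alg)
  }
})

test_that("LOOCV runs n leak-free folds and averages single-sample errors", {
  set.seed(14)
  x <- matrix(rnorm(10), 5, 2,
              dimnames = list(paste0("s", 1:5), c("a", "b")))
  y <- rnorm(5)
  log_env <- new.env()
  res <- loocv(counting_fitter(log_env), x, y)
  ## exactly n fits, each on n-1 samples, fold i never sees sample i
  expect_length(log_env$fits, 5)
  for (i in 1:5) {
    expect_equal(log_env$fits[[i]]$n, 4)
    expect_false(paste0("s", i) %in% log_env$fits[[i]]$ids)
  }
  ## the score is the mean absolute leave-one-out error
  mus <- vapply(1:5, function(i) mean(y[-i]), numeric(1))
  expect_equal(as.numeric(res), mean(abs(y - mus)))

  ## zero targets with a zero predictor score exactly 0
  zero_fitter <- function(x, y, hyperparameters, randomState)
    list(predict = function(newx) rep(0, nrow(newx)), importance = NULL)
  expect_equal(as.numeric(loocv(zero_fitter, x, rep(0, 5))), 0)
  expect_error(loocv(zero_fitter, x[1:2, ], y[1:2]), "n >= 3")
})

test_that("LOOCV of a 1-NN predictor matches the hand-enumerated folds", {
  x <- matrix(c(0, 1, 10, 11, 20), 5, 1, dimnames = list(NULL, "f"))
  y <- c(0, 1, 10, 11, 20)
  ## hand enumeration: each point's nearest other point predicts it
  hand <- mean(abs(c(0 - 1, 1 - 0, 10 - 11, 11 - 10, 20 - 11)))
  expect_equal(as.numeric(loocv(onenn_fitter, x, y)), hand)
})

test_that("lasso LOOCV error vanishes on noiseless data as lambda -> 0", {
  set.seed(15)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- x[, 1] + 2 * x[, 2]
  loos <- vapply(c(0.5, 0.05, 1e-4), function(lam)
    as.numeric(loocv("lasso", x, y, list(lambda = lam))), numeric(1))
  expect_true(all(diff(loos) < 0))
  expect_lt(loos[3], 1e-2)
})

test_that("the experiment grid covers the configured cells and records skips", {
  sp <- syntheticSpec(nSamples = 30, nDescriptors = 6, nFpBits = 16,
                      planted = c(desc_0001 = 1), noiseSd = 0.3, seed = 21)
  ds <- generateDataset(sp)
  tabs <- soacqspr:::.split_by_kind(ds$table)
  cfg <- experimentConfig(algorithms = c("lasso", "random_forest", "catboost"),
                          randomStates = c(0L, 1L), loocv = FALSE)
  runs <- runExperiment(tabs$descriptors, tabs$fingerprints, ds$y, cfg)
  ## 2 available algorithms x 2 sets x 2 states; catboost cells skipped
  expect_length(runs, 8)
  fails <- attr(runs, "failures")
  expect_equal(nrow(fails), 4)
  expect_true(all(fails$algorithm == "catboost" & fails$type == "skipped"))
  grid <- resultsGrid(runs, means = FALSE)
  expect_equal(nrow(grid), 8)
  expect_true(all(grid$rmse >= 0))
  expect_true(all(grid$r2 <= 1))
  ## partition bookkeeping on every run
  for (r in runs) {
    expect_length(r@trainIds, 27)
    expect_length(r@testIds, 3)
    expect_length(intersect(r@trainIds, r@testIds), 0)
  }
  ## grid shape arithmetic: dropping an algorithm shrinks the grid
  cfg2 <- experimentConfig(algorithms = "lasso", randomStates = 0L,
                           loocv = FALSE)
  expect_length(runExperiment(tabs$descriptors, NULL, ds$y, cfg2), 1)
})
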