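test_that("importance extraction honours the algorithm contract", {
  r <- fake_run(c(a = 2, b = 1), r2 = 0.5, algorithm = "lasso")
  expect_identical(extractImportance(r), c(a = 2, b = 1))
  dnn <- fake_run(numeric(), r2 = 0.5, algorithm = "dnn")
  expect_error(extractImportance(dnn), "dnn")
  ## lasso coefficients enter as absolute values via the fit adapter
  set.seed(20)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- -2 * x[, 1] + 1 * x[, 2]
  fit <- fitModel("lasso", x, y, list(lambda = 1e-3))
  expect_equal(unname(fit$importance[c("a", "b")]), c(2, 1), tolerance = 0.05)
  expect_true(all(fit$importance >= 0))
})

test_that("rank-to-score maps 10..1 to the positive top-10", {
  imp <- setNames(c(20, 10, 5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.25, 0.1),
                  paste0("f", sprintf("%02d", 1:12)))
  sc <- scoreRanking(imp)
  expect_equal(unname(sc["f01"]), 10)  # rank 1
  expect_equal(unname(sc["f03"]), 8)   # rank 3
  expect_equal(unname(sc["f10"]), 1)   # rank 10
  expect_equal(unname(sc["f11"]), 0)   # rank 11
  expect_equal(sum(sc), 55)            # full 10+9+...+1
  ## zero importance is never scored, even with < 10 features
  sc2 <- scoreRanking(c(a = 3, b = 0, c = 1))
  expect_equal(unname(sc2), c(10, 0, 9))
  ## ties broken stably by feature name
  sc3 <- scoreRanking(c(z = 1, a = 1, m = 1))
  expect_equal(unname(sc3[c("a", "m", "z")]), c(10, 9, 8))
  expect_error(scoreRanking(c(a = -1)), "importance")
})

test_that("consensus sums eligible models only", {
  r_good <- fake_run(c(x = 5, y = 3, z = 1), r2 = 0.4)
  r_neg <- fake_run(c(x = 100, w = 50), r2 = -0.2)
  r_other <- fake_run(c(y = 9, x = 2), r2 = 0.0, algorithm = "xgboost")
  ## single eligible model: consensus equals its scores
  c1 <- buildConsensus(list(r_good))
  expect_equal(consensusScores(c1), c(x = 10, y = 9, z = 8))
  ## a negative-r2 run contributes nothing
  c2 <- buildConsensus(list(r_good, r_neg))
  expect_equal(consensusScores(c2), c(x = 10, y = 9, z = 8))
  expect_length(eligibleModels(c2), 1)
  ## r2 = 0 is eligible (the filter is >= 0); scores add across models
  c3 <- buildConsensus(list(r_good, r_other))
  expect_equal(unname(consensusScores(c3)["y"]), 9 + 10)
  expect_equal(unname(consensusScores(c3)["x"]), 10 + 9)
  ## two models both ranking x first give it 20
  c4 <- buildConsensus(list(r_good, fake_run(c(x = 7), r2 = 0.1,
                                             randomState = 1L)))
  expect_equal(unname(consensusScores(c4)["x"]), 20)
  ## zero eligible models: empty consensus with a warning, not an error
  expect_warning(c5 <- buildConsensus(list(r_neg)), "eligible")
  expect_length(consensusScores(c5), 0)
})

test_that("consensus equals brute-force enumeration on random instances", {
  set.seed(21)
  feats <- paste0("f", 1:5)
  for (case in 1:100) {
    n_models <- sample(1:3, 1)
    imps <- list(); r2s <- numeric(); runs <- list()
    for (m in seq_len(n_models)) {
      v <- setNames(round(runif(5, 0, 4), 1), feats)
      v[sample(5, sample(0:3, 1))] <- 0
      r2 <- round(runif(1, -0.5, 1), 2)
      imps[[m]] <- v; r2s[m] <- r2
      runs[[m]] <- fake_run(v, r2, randomState = m)
    }
    got <- consensusScores(suppressWarnings(buildConsensus(runs)))
    want <- oracle_consensus(imps, r2s)
    if (length(want) == 0) expect_length(got, 0)
    else expect_equal(got, want, info = sprintf("case %d", case))
  }
})

test_that("consensus score conservation, bounds and monotonicity hold", {
  set.seed(22)
  feats <- sprintf("f%02d", 1:15)
  runs <- lapply(1:4, function(m)
    fake_run(setNames(runif(15, 0.1, 5), feats), r2 = runif(1, 0, 1),
             randomState = m))
  cons <- buildConsensus(runs)
  ## >= 10 positive features per model: each contributes exactly 55
  expect_equal(sum(consensusScores(cons)), 55 * 4)
  expect_true(all(consensusScores(cons) <= 10 * length(eligibleModels(cons))))
  expect_true(all(consensusScores(cons) >= 0))
  ## adding an eligible model never decreases any feature's score
  more <- c(runs, list(fake_run(setNames(runif(15), feats), r2 = 0.3,
                                randomState = 99L)))
  cons2 <- buildConsensus(more)
  common <- names(consensusScores(cons))
  s1 <- consensusScores(cons)[common]
  s2 <- consensusScores(cons2)[common]
  s2[is.na(s2)] <- 0
  expect_true(all(s2 >= s1))
})

test_that("top-k truncates without padding and keeps order", {
  r <- fake_run(setNames(c(5, 4, 3), c("a", "b", "c")), r2 = 0.9)
  cons <- buildConsensus(list(r))
  top2 <- topFeatures(cons, 2)
  expect_equal(top2$feature, c("a", "b"))
  expect_equal(top2$score, c(10, 9))
  ## k larger than the scored set: all scored features, nothing more
  top9 <- topFeatures(cons, 9)
  expect_equal(nrow(top9), 3)
  expect_true(all(diff(top9$score) <= 0))
  expect_equal(topFeatures(cons, 1)$feature, "a")
  ## serialization round-trip
  p <- withr::local_tempfile(fileext = ".csv")
  writeConsensus(cons, p)
  df <- utils::read.csv(p)
  expect_equal(df$feature, c("a", "b", "c"))
  expect_equal(df$score, c(10, 9, 8))
})

test_that("a dominant planted feature tops tree-ensemble importance", {
  ## empirical recovery: one strong feature among noise, many seeded fits
  hits <- 0
  for (rep in 1:20) {
    sp <- syntheticSpec(nSamples = 60, nDescriptors = 8,
                        planted = c(desc_0003 = 2), noiseSd = 0.5,
                        seed = 300 + rep)
    ds <- generateDataset(sp)
    fit <- fitModel("random_forest", featureMatrix(ds$table), unname(ds$y),
                    list(ntree = 150L), randomState = rep)
    if (names(which.max(fit$importance)) == "desc_0003") hits <- hits + 1
  }
  expect_gte(hits, 18)
})
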