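test_that("zero-variance features are removed, others untouched", {
  set.seed(2)
  m <- cbind(matrix(rnorm(40), 10, 4,
                    dimnames = list(sprintf("s%02d", 1:10), paste0("v", 1:4))),
             const1 = 5, const2 = 0, const3 = -1)
  res <- dropZeroVariance(make_ft(m))
  expect_setequal(removedFeatures(res$report)$feature,
                  c("const1", "const2", "const3"))
  expect_equal(nrow(removedFeatures(res$report)), 3)
  expect_identical(featureMatrix(res$table), m[, paste0("v", 1:4)])
  ## identity on clean tables
  res2 <- dropZeroVariance(res$table)
  expect_equal(nrow(removedFeatures(res2$report)), 0)
  expect_identical(featureMatrix(res2$table), featureMatrix(res$table))
})

test_that("duplicate columns collapse to the name-order-first survivor", {
  set.seed(3)
  base <- rnorm(8)
  m <- cbind(b_dup = base, a_dup = base, z_dup = base, other = rnorm(8))
  res <- dropDuplicates(make_ft(m))
  rem <- removedFeatures(res$report)
  expect_setequal(rem$feature, c("b_dup", "z_dup"))  # a_dup survives
  expect_true(all(rem$partner == "a_dup"))
  expect_setequal(keptFeatures(res$report), c("a_dup", "other"))
  ## brute-force check: no two surviving columns identical
  x <- featureMatrix(res$table)
  for (i in seq_len(ncol(x) - 1))
    for (j in seq(i + 1, ncol(x)))
      expect_false(identical(x[, i], x[, j]))
  ## identity when all distinct
  res2 <- dropDuplicates(res$table)
  expect_equal(nrow(removedFeatures(res2$report)), 0)
})

test_that("correlation pruning breaks proportional pairs and certifies output", {
  set.seed(4)
  a <- rnorm(20)
  m <- cbind(a = a, b = 2 * a + 1, c = rnorm(20))
  res <- correlationPrune(make_ft(m), threshold = 0.95)
  rem <- removedFeatures(res$report)
  expect_equal(nrow(rem), 1)
  expect_true(rem$feature %in% c("a", "b"))
  expect_equal(rem$abs_r, 1, tolerance = 1e-12)
  r <- abs(cor(featureMatrix(res$table))); diag(r) <- 0
  expect_lt(max(r), 0.95)
  ## identity when no pair exceeds the threshold
  res2 <- correlationPrune(res$table, threshold = 0.95)
  expect_equal(nrow(removedFeatures(res2$report)), 0)
  ## zero-variance input is a precondition error pointing at the right stage
  expect_error(correlationPrune(make_ft(cbind(m, k = 1)), 0.95),
               "dropZeroVariance")
})

test_that("greedy removal sequence matches the brute-force oracle", {
  set.seed(5)
  for (case in 1:30) {
    n <- sample(10:25, 1)
    p <- sample(3:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    ## plant correlation chains of varying strength
    if (p >= 4) {
      x[, 2] <- x[, 1] + rnorm(n, sd = 0.05)
      x[, 3] <- x[, 1] + rnorm(n, sd = 0.2)
    }
    colnames(x) <- sprintf("f%02d", seq_len(p))
    rownames(x) <- sprintf("s%02d", seq_len(n))
    thr <- sample(c(0.8, 0.9, 0.95), 1)
    got <- removedFeatures(correlationPrune(make_ft(x), thr)$report)$feature
    expect_identical(got, oracle_corr_prune(x, thr),
                     info = sprintf("case %d (n=%d p=%d thr=%.2f)", case, n, p, thr))
  }
})

test_that("selectFeatures composes the stages in order and is idempotent", {
  set.seed(6)
  a <- rnorm(30)
  m <- cbind(a = a, a_copy = a, b = 3 * a, c = rnorm(30), d = rnorm(30),
             konst = 7)
  res <- selectFeatures(make_ft(m), threshold = 0.95)
  rem <- removedFeatures(res$report)
  expect_identical(unique(rem$stage)[order(match(unique(rem$stage),
    c("zero_variance", "duplicate", "correlation")))],
    c("zero_variance", "duplicate", "correlation"))
  expect_true("konst" %in% rem$feature[rem$stage == "zero_variance"])
  expect_true("a_copy" %in% rem$feature[rem$stage == "duplicate"])
  ## conservation: removed + kept = input features, disjoint
  expect_setequal(c(rem$feature, keptFeatures(res$report)), colnames(m))
  expect_length(intersect(rem$feature, keptFeatures(res$report)), 0)
  ## idempotence
  res2 <- selectFeatures(res$table, threshold = 0.95)
  expect_identical(featureMatrix(res2$table), featureMatrix(res$table))
  expect_equal(nrow(removedFeatures(res2$report)), 0)
  ## already-clean table is untouched
  clean <- rand_ft(25, 5, seed = 8)
  res3 <- selectFeatures(clean, threshold = 0.95)
  expect_identical(featureMatrix(res3$table), featureMatrix(clean))
})

test_that("fingerprint bits bypass the correlation stage", {
  set.seed(9)
  a <- rnorm(40)
  desc <- cbind(d1 = a, d2 = 2 * a, d3 = rnorm(40))
  bits <- cbind(fp_0001 = rep(c(0, 1), 20), fp_0002 = rep(c(0, 1), 20))
  tab <- featureTable(cbind(desc, bits),
                      kind = rep(c("descriptor", "fingerprint_bit"), c(3, 2)))
  res <- selectFeatures(tab, threshold = 0.9)
  rem <- removedFeatures(res$report)
  ## the perfectly correlated fingerprint pair survives the correlation
  ## stage (fp_0002 is a duplicate here, so it is removed at that stage);
  ## no correlation-stage removal may touch a fingerprint bit
  expect_false(any(startsWith(rem$feature[rem$stage == "correlation"], "fp_")))
  expect_true(any(rem$feature %in% c("d1", "d2")))
  ## report serialization round-trips through delimited text
  p <- withr::local_tempfile(fileext = ".csv")
  writeSelectionReport(res$report, p)
  expect_identical(utils::read.csv(p)$feature, rem$feature)
})
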