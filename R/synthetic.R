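#' @include AllClasses.R FeatureTable.R
NULL

.feature_names <- function(prefix, n) {
  if (n == 0L) character() else sprintf("%s_%04d", prefix, seq_len(n))
}

#' Specify a synthetic QSPR-like benchmark dataset
#'
#' Builds a \linkS4class{SyntheticSpec}: the full recipe (sizes, correlation
#' blocks, planted sparse linear signal, noise, seed) for a dataset with the
#' statistical structure the pipeline assumes — a small sample of compounds,
#' a few dozen continuous descriptors arranged in correlated blocks, and a
#' large sparse binary fingerprint block.
#'
#' @param nSamples,nDescriptors,nFpBits dataset dimensions.
#' @param blocks data.frame with columns \code{size} and \code{rho}:
#'   equicorrelated blocks of descriptors (pairwise correlation rho),
#'   occupying the leading descriptor columns in order; remaining descriptors
#'   are independent standard normals.
#' @param fpDensity Bernoulli probability that a fingerprint bit is 1.
#' @param planted named numeric of true coefficients (names must be generated
#'   feature names, e.g. \code{"desc_0021"}).
#' @param noiseSd standard deviation of the additive Gaussian noise on y.
#' @param seed master seed; every generation step derives its own stream
#'   from (seed, operation tag), so outputs are reproducible and adding new
#'   operations never shifts existing ones.
#' @return A validated \linkS4class{SyntheticSpec}.
#' @seealso \code{\link{defaultSyntheticSpec}} for the study-sized default.
#' @export
syntheticSpec <- function(nSamples, nDescriptors, nFpBits = 0L,
                          blocks = data.frame(size = integer(), rho = numeric()),
                          fpDensity = 0.05, planted = numeric(),
                          noiseSd = 1, seed = 0L) {
  methods::new("SyntheticSpec",
               nSamples = .assert_count(nSamples, "nSamples"),
               nDescriptors = .assert_count(nDescriptors, "nDescriptors"),
               nFpBits = .assert_count(nFpBits, "nFpBits"),
               blocks = as.data.frame(blocks), fpDensity = fpDensity,
               planted = planted, noiseSd = noiseSd,
               seed = .assert_count(seed, "seed"))
}

#' Study-sized default synthetic specification
#'
#' The default conditions emulate the target application: 74 samples, 60
#' continuous descriptors of which the leading 15 form three correlated
#' blocks, 2048 sparse fingerprint bits, and 5 planted informative
#' descriptors (outside the correlated blocks) whose linear signal explains
#' a fixed share of the variance of y.
#'
#' @param seed master seed.
#' @param targetR2 fraction of var(y) explained by the planted linear signal;
#'   the noise standard deviation is set so that
#'   \code{var(signal)/(var(signal)+noiseSd^2) = targetR2} under independent
#'   standard-normal planted features. Default 0.8.
#' @return A \linkS4class{SyntheticSpec}.
#' @examples
#' sp <- defaultSyntheticSpec(seed = 1)
#' sp
#' @export
defaultSyntheticSpec <- function(seed = 0L, targetR2 = 0.8) {
  planted <- c(desc_0021 = 1.0, desc_0022 = -0.8, desc_0023 = 0.8,
               desc_0024 = 0.6, desc_0025 = -0.6)
  varsig <- sum(planted^2)  # planted features independent N(0,1)
  noiseSd <- sqrt(varsig * (1 - targetR2) / targetR2)
  syntheticSpec(
    nSamples = 74L, nDescriptors = 60L, nFpBits = 2048L,
    blocks = data.frame(size = c(6L, 5L, 4L), rho = c(0.9, 0.8, 0.6)),
    fpDensity = 0.05, planted = planted, noiseSd = noiseSd, seed = seed)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d samples, %d descriptors (%d blocks), ",
                     "%d fp bits (density %.3g)\n  planted: %d features, ",
                     "noiseSd = %.4g, seed = %d\n"),
              object@nSamples, object@nDescriptors, nrow(object@blocks),
              object@nFpBits, object@fpDensity, length(object@planted),
              object@noiseSd, object@seed))
})

#' Ground truth of a synthetic dataset
#'
#' @param coefficients named numeric of true coefficients.
#' @param noiseSd noise standard deviation.
#' @return A \linkS4class{GroundTruth}.
#' @export
groundTruth <- function(coefficients = numeric(), noiseSd = 0) {
  methods::new("GroundTruth", coefficients = coefficients, noiseSd = noiseSd)
}

#' @describeIn groundTruth Extract the ground truth implied by a spec.
#' @param spec A \linkS4class{SyntheticSpec}.
#' @export
groundTruthFromSpec <- function(spec) {
  groundTruth(coefficients = spec@planted, noiseSd = spec@noiseSd)
}

#' Informative feature set
#'
#' @param x A \linkS4class{GroundTruth}.
#' @return Feature names with nonzero true coefficient.
#' @rdname informativeSet
#' @export
setMethod("informativeSet", "GroundTruth",
          function(x) names(x@coefficients)[x@coefficients != 0])

#' Generate a synthetic feature table
#'
#' Descriptor columns are drawn from a multivariate normal: each declared
#' block is equicorrelated at its rho (realized through the Cholesky factor
#' of the block's correlation matrix, i.e. a Gaussian copula with standard
#' normal margins), remaining descriptors are independent N(0,1).
#' Fingerprint bits are i.i.d. Bernoulli(fpDensity), independent of the
#' descriptors. Deterministic given \code{spec@seed}.
#'
#' @param spec A valid \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{FeatureTable} with \code{nSamples} rows and
#'   \code{nDescriptors + nFpBits} features named \code{desc_####} /
#'   \code{fp_####}.
#' @examples
#' sp <- syntheticSpec(nSamples = 10, nDescriptors = 4, nFpBits = 8,
#'                     blocks = data.frame(size = 2, rho = 0.9), seed = 7)
#' ft <- generateFeatureTable(sp)
#' dim(featureMatrix(ft))
#' @export
generateFeatureTable <- function(spec) {
  methods::validObject(spec)
  n <- spec@nSamples
  p <- spec@nDescriptors
  desc <- .with_op_seed(spec@seed, "descriptors", {
    z <- matrix(stats::rnorm(n * p), n, p)
    offset <- 0L
    for (i in seq_len(nrow(spec@blocks))) {
      sz <- spec@blocks$size[i]
      rho <- spec@blocks$rho[i]
      if (sz > 1L && rho > 0) {
        sigma <- matrix(rho, sz, sz); diag(sigma) <- 1
        idx <- offset + seq_len(sz)
        z[, idx] <- z[, idx, drop = FALSE] %*% chol(sigma)
      }
      offset <- offset + sz
    }
    z
  })
  fp <- .with_op_seed(spec@seed, "fingerprints", {
    matrix(stats::rbinom(n * spec@nFpBits, 1L, spec@fpDensity), n, spec@nFpBits)
  })
  m <- cbind(desc, fp)
  dimnames(m) <- list(sprintf("sample_%04d", seq_len(n)),
                      c(.feature_names("desc", p), .feature_names("fp", spec@nFpBits)))
  featureTable(m, kind = rep(c("descriptor", "fingerprint_bit"),
                             c(p, spec@nFpBits)))
}

#' Generate targets from a feature table and a ground truth
#'
#' \code{y_i = sum_f coef_f x_if + eps_i}, \code{eps ~ N(0, noiseSd^2)},
#' deterministic given \code{seed}.
#'
#' @param table A \linkS4class{FeatureTable}.
#' @param truth A \linkS4class{GroundTruth}; every coefficient name must be a
#'   feature of \code{table}.
#' @param seed integer seed for the noise stream.
#' @return Named numeric vector of targets, one per sample.
#' @export
generateTargets <- function(table, truth, seed = 0L) {
  methods::validObject(truth)
  x <- featureMatrix(table)
  nm <- names(truth@coefficients)
  missing <- setdiff(nm, colnames(x))
  if (length(missing))
    .validation_error(sprintf("planted: feature(s) not in table: %s",
                              paste(missing, collapse = ", ")),
                      field = "planted")
  signal <- if (length(nm))
    drop(x[, nm, drop = FALSE] %*% truth@coefficients) else rep(0, nrow(x))
  eps <- .with_op_seed(seed, "targets", stats::rnorm(nrow(x), 0, truth@noiseSd))
  y <- signal + eps
  names(y) <- rownames(x)
  y
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: feature table, targets and ground truth in one call,
#' all driven by \code{spec@seed}.
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @return List with elements \code{table} (\linkS4class{FeatureTable}),
#'   \code{y} (named numeric) and \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateDataset <- function(spec) {
  table <- generateFeatureTable(spec)
  truth <- groundTruthFromSpec(spec)
  y <- generateTargets(table, truth, seed = spec@seed)
  list(table = table, y = y, truth = truth)
}

#' Write a synthetic dataset as delimited text
#'
#' Writes the feature table (CSV + kinds sidecar), targets (CSV with columns
#' \code{sample_id,y}) and the ground truth as a small key=value text file.
#'
#' @param dataset result of \code{\link{generateDataset}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(features = file.path(dir, "features.csv"),
             targets = file.path(dir, "targets.csv"),
             truth = file.path(dir, "ground_truth.txt"))
  writeFeatureTable(dataset$table, paths[["features"]])
  utils::write.csv(data.frame(sample_id = names(dataset$y), y = unname(dataset$y)),
                   paths[["targets"]], row.names = FALSE)
  tr <- dataset$truth
  lines <- c(sprintf("noise_sd=%.17g", tr@noiseSd),
             sprintf("coef.%s=%.17g", names(tr@coefficients), tr@coefficients))
  writeLines(lines, paths[["truth"]])
  invisible(paths)
}
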