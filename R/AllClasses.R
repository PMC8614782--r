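#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.FEATURE_KINDS <- c("descriptor", "fingerprint_bit")

#' FeatureTable: samples-by-features container
#'
#' The unit of data passed between all pipeline stages: a
#' \linkS4class{SummarizedExperiment} whose rows are features (each tagged as
#' a continuous \code{descriptor} or a binary \code{fingerprint_bit}) and
#' whose columns are compounds/samples. Fingerprint rows may contain only 0/1
#' and no value may be missing or non-finite.
#'
#' Use \code{\link{featureTable}} to construct one from a samples x features
#' matrix, \code{\link{featureMatrix}} to get that matrix back, and
#' \code{\link{featureKind}} for the per-feature kind tags.
#'
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  fn <- rownames(object)
  if (is.null(fn) || anyNA(fn) || any(fn == ""))
    msg <- c(msg, "feature names: all features must be named")
  if (anyDuplicated(fn))
    msg <- c(msg, sprintf("feature names: duplicated (%s)",
                          paste(unique(fn[duplicated(fn)]), collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!"kind" %in% colnames(rd)) {
    msg <- c(msg, "kind: rowData must carry a 'kind' column")
  } else {
    kind <- rd$kind
    if (!all(kind %in% .FEATURE_KINDS))
      msg <- c(msg, sprintf("kind: values must be one of {%s}",
                            paste(.FEATURE_KINDS, collapse = ", ")))
    x <- SummarizedExperiment::assay(object, "X")
    if (!all(is.finite(x))) {
      msg <- c(msg, "values: all feature values must be finite")
    } else {
      fp <- kind == "fingerprint_bit"
      if (any(fp) && !all(x[fp, , drop = FALSE] %in% c(0, 1)))
        msg <- c(msg, "values: fingerprint_bit rows must contain only 0/1")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SyntheticSpec: recipe for a ground-truth benchmark dataset
#'
#' Captures everything needed to regenerate a synthetic dataset emulating a
#' small QSPR study: sample count, continuous descriptor-like features in
#' equicorrelated blocks, sparse Bernoulli fingerprint-like bits, a sparse
#' planted linear signal, Gaussian noise, and a seed.
#'
#' @slot nSamples number of samples (>= 3).
#' @slot nDescriptors number of continuous descriptor features.
#' @slot nFpBits number of binary fingerprint bits.
#' @slot blocks data.frame with columns \code{size}, \code{rho}; blocks of
#'   descriptors sharing pairwise correlation rho in [0, 1). Blocks occupy
#'   the leading descriptor columns in order.
#' @slot fpDensity probability that a fingerprint bit is 1.
#' @slot planted named numeric; true nonzero coefficients keyed by feature
#'   name (\code{desc_####} / \code{fp_####}).
#' @slot noiseSd standard deviation of additive Gaussian noise on y.
#' @slot seed integer master seed; each operation derives its own stream.
#' @aliases SyntheticSpec-class
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(nSamples = "integer", nDescriptors = "integer",
                 nFpBits = "integer", blocks = "data.frame",
                 fpDensity = "numeric", planted = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nSamples < 3L) msg <- c(msg, "nSamples: must be >= 3")
  if (object@nDescriptors < 0L) msg <- c(msg, "nDescriptors: must be >= 0")
  if (object@nFpBits < 0L) msg <- c(msg, "nFpBits: must be >= 0")
  b <- object@blocks
  if (nrow(b)) {
    if (!all(c("size", "rho") %in% colnames(b)))
      msg <- c(msg, "blocks: needs columns 'size' and 'rho'")
    else {
      if (any(b$size < 1) || sum(b$size) > object@nDescriptors)
        msg <- c(msg, "blocks: sum of block sizes must be <= nDescriptors")
      if (any(b$rho < 0) || any(b$rho >= 1))
        msg <- c(msg, "blocks: rho must lie in [0, 1)")
    }
  }
  if (is.na(object@fpDensity) || object@fpDensity < 0 || object@fpDensity > 1)
    msg <- c(msg, "fpDensity: must lie in [0, 1]")
  if (is.na(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd: must be >= 0")
  if (length(object@planted)) {
    nm <- names(object@planted)
    if (is.null(nm) || any(nm == ""))
      msg <- c(msg, "planted: coefficients must be named by feature")
    else {
      known <- c(.feature_names("desc", object@nDescriptors),
                 .feature_names("fp", object@nFpBits))
      bad <- setdiff(nm, known)
      if (length(bad))
        msg <- c(msg, sprintf("planted: unknown feature name(s) %s",
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' GroundTruth: the generating model behind a synthetic dataset
#'
#' @slot coefficients named numeric map feature -> true coefficient.
#' @slot noiseSd noise standard deviation used at generation.
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(coefficients = "numeric", noiseSd = "numeric"))

setValidity("GroundTruth", function(object) {
  if (length(object@coefficients) &&
      (is.null(names(object@coefficients)) || any(names(object@coefficients) == "")))
    return("coefficients: must be a named numeric vector")
  if (is.na(object@noiseSd) || object@noiseSd < 0)
    return("noiseSd: must be >= 0")
  TRUE
})

#' CompoundRecord: one molecule of the input table
#'
#' Holds the identifiers, isomeric SMILES and rate data for one compound.
#' The modelling target is \code{y = ln(rate ratio)}: either \code{ln(soac)}
#' (SOAC is already the ratio of the compound's singlet-oxygen quenching rate
#' constant to alpha-tocopherol's) or \code{ln(kQ / kRef)}.
#'
#' @slot id compound identifier.
#' @slot name human-readable name (may be empty).
#' @slot smiles isomeric SMILES string.
#' @slot kQ quenching rate constant in 1/(M s); NA when only SOAC is known.
#' @slot soac SOAC value (dimensionless rate ratio); NA when only kQ known.
#' @slot y derived target, ln(rate ratio).
#' @aliases CompoundRecord-class
#' @exportClass CompoundRecord
setClass("CompoundRecord",
  representation(id = "character", name = "character", smiles = "character",
                 kQ = "numeric", soac = "numeric", y = "numeric"))

setValidity("CompoundRecord", function(object) {
  msg <- character()
  if (is.na(object@kQ) && is.na(object@soac))
    msg <- c(msg, "kQ/soac: at least one of kQ or soac must be present")
  if (!is.na(object@kQ) && object@kQ <= 0) msg <- c(msg, "kQ: must be > 0")
  if (!is.na(object@soac) && object@soac <= 0) msg <- c(msg, "soac: must be > 0")
  if (!is.finite(object@y)) msg <- c(msg, "y: must be finite")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DescriptorSet: one compound's molecular descriptors
#'
#' Quantum-chemical scalars (frontier orbital energies, heat of formation,
#' dipole moment) plus a named vector of 2-D topological/physicochemical
#' descriptors.
#'
#' @slot homo HOMO energy (eV).
#' @slot lumo LUMO energy (eV).
#' @slot gap lumo - homo (eV); validity enforces the identity to 1e-9.
#' @slot heatOfFormation kcal/mol.
#' @slot dipole Debye.
#' @slot descriptors2d named numeric of 2-D descriptors.
#' @aliases DescriptorSet-class
#' @exportClass DescriptorSet
setClass("DescriptorSet",
  representation(homo = "numeric", lumo = "numeric", gap = "numeric",
                 heatOfFormation = "numeric", dipole = "numeric",
                 descriptors2d = "numeric"))

setValidity("DescriptorSet", function(object) {
  vals <- c(object@homo, object@lumo, object@gap, object@heatOfFormation,
            object@dipole, object@descriptors2d)
  if (!all(is.finite(vals))) return("all descriptor values must be finite")
  if (abs(object@gap - (object@lumo - object@homo)) > 1e-9)
    return("gap: must equal lumo - homo (within 1e-9)")
  TRUE
})

## -- descriptor backends ----------------------------------------------------

#' Descriptor backends
#'
#' A backend computes a \linkS4class{DescriptorSet} from a SMILES string.
#' Three interchangeable implementations exist:
#' \describe{
#'   \item{\code{StubBackend}}{deterministic pseudo-descriptors hashed from
#'     the (optionally canonicalized) SMILES string; no chemistry, used for
#'     testing and pipeline plumbing.}
#'   \item{\code{ToolkitBackend}}{real 2-D descriptors from the
#'     cheminformatics toolkit (ChemmineR/OpenBabel); quantum fields come
#'     from the configured quantum source (stub by default, or a
#'     semiempirical engine).}
#'   \item{\code{QuantumBackend}}{subprocess adapter around an external
#'     semiempirical engine (PM7/MOPAC-style): writes an input deck, runs the
#'     executable, parses HOMO/LUMO/heat of formation/dipole from the output
#'     listing. Raises a capability error when no executable is available.}
#' }
#' @aliases DescriptorBackend-class StubBackend-class ToolkitBackend-class
#'   QuantumBackend-class
#' @exportClass DescriptorBackend
#' @exportClass StubBackend
#' @exportClass ToolkitBackend
#' @exportClass QuantumBackend
setClass("DescriptorBackend", representation("VIRTUAL", id = "character"))
setClass("StubBackend", contains = "DescriptorBackend")
setClass("ToolkitBackend", contains = "DescriptorBackend",
         representation(quantumSource = "character", executable = "character"))
setClass("QuantumBackend", contains = "DescriptorBackend",
         representation(executable = "character", keywords = "character"))

## -- selection --------------------------------------------------------------

#' SelectionReport: audit trail of descriptor pruning
#'
#' @slot removed data.frame with columns \code{feature}, \code{stage}
#'   (zero_variance | duplicate | correlation), \code{partner} (NA outside
#'   the correlation stage) and \code{abs_r} (|Pearson r| at removal, NA
#'   outside the correlation stage), in removal order.
#' @slot kept character; surviving feature names in table order.
#' @slot threshold correlation cutoff used (NA when the stage did not run).
#' @aliases SelectionReport-class
#' @exportClass SelectionReport
setClass("SelectionReport",
  representation(removed = "data.frame", kept = "character",
                 threshold = "numeric"))

setValidity("SelectionReport", function(object) {
  msg <- character()
  need <- c("feature", "stage", "partner", "abs_r")
  if (!all(need %in% colnames(object@removed)))
    msg <- c(msg, sprintf("removed: needs columns %s", paste(need, collapse = ", ")))
  else {
    if (length(intersect(object@removed$feature, object@kept)))
      msg <- c(msg, "removed/kept: must be disjoint")
    corr <- object@removed$stage == "correlation"
    if (any(corr)) {
      if (anyNA(object@removed$partner[corr]) || anyNA(object@removed$abs_r[corr]))
        msg <- c(msg, "removed: correlation-stage entries need partner and abs_r")
      else if (!is.na(object@threshold) &&
               any(object@removed$abs_r[corr] < object@threshold - 1e-12))
        msg <- c(msg, "removed: correlation-stage abs_r must be >= threshold")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

## -- model runs -------------------------------------------------------------

#' ModelRun: one (algorithm x feature-set x random-state) evaluation
#'
#' @slot algorithm one of xgboost, lightgbm, catboost, random_forest,
#'   adaboost, lasso, dnn.
#' @slot featureSet "descriptor" or "fingerprint".
#' @slot randomState integer split/fit seed.
#' @slot hyperparameters full hyperparameter list used.
#' @slot r2 test-set coefficient of determination (may be negative; NA when
#'   undefined, i.e. constant test targets).
#' @slot rmse test-set root mean squared error (units of y).
#' @slot rmseLoo leave-one-out CV score on the training partition (mean of
#'   per-fold single-sample RMSEs); NA when LOOCV was not requested.
#' @slot importance named nonnegative numeric aligned to the feature set;
#'   length 0 for algorithms without importances (dnn).
#' @slot predictions named numeric of test-set predictions.
#' @slot trainIds,testIds sample ids of the partition.
#' @aliases ModelRun-class
#' @exportClass ModelRun
setClass("ModelRun",
  representation(algorithm = "character", featureSet = "character",
                 randomState = "integer", hyperparameters = "list",
                 r2 = "numeric", rmse = "numeric", rmseLoo = "numeric",
                 importance = "numeric", predictions = "numeric",
                 trainIds = "character", testIds = "character"))

setValidity("ModelRun", function(object) {
  msg <- character()
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2: must be <= 1")
  if (!is.na(object@rmse) && object@rmse < 0) msg <- c(msg, "rmse: must be >= 0")
  if (!is.na(object@rmseLoo) && object@rmseLoo < 0)
    msg <- c(msg, "rmseLoo: must be >= 0")
  if (length(object@importance) && any(object@importance < 0))
    msg <- c(msg, "importance: values must be >= 0")
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "trainIds/testIds: must be disjoint")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ConsensusRanking: summed rank-score feature importances
#'
#' Per eligible model (test R^2 >= 0, importance-capable algorithm), the
#' top-10 positive-importance features receive scores 10, 9, ..., 1 by rank;
#' scores are summed per feature across models.
#'
#' @slot scores named numeric, sorted by decreasing total score (ties by
#'   feature name).
#' @slot contributors named list: feature -> data.frame(model, rank, score).
#' @slot eligibleModels character ids "algorithm/featureSet/randomState" of
#'   the contributing models.
#' @aliases ConsensusRanking-class
#' @exportClass ConsensusRanking
setClass("ConsensusRanking",
  representation(scores = "numeric", contributors = "list",
                 eligibleModels = "character"))

setValidity("ConsensusRanking", function(object) {
  msg <- character()
  if (length(object@scores)) {
    if (is.null(names(object@scores))) msg <- c(msg, "scores: must be named")
    if (is.unsorted(rev(object@scores))) msg <- c(msg, "scores: must be non-increasing")
    if (any(object@scores < 0)) msg <- c(msg, "scores: must be >= 0")
    if (any(object@scores > 10 * max(1L, length(object@eligibleModels))))
      msg <- c(msg, "scores: exceed 10 x number of eligible models")
    bad <- vapply(names(object@scores), function(f) {
      ct <- object@contributors[[f]]
      is.null(ct) || !isTRUE(all.equal(sum(ct$score), unname(object@scores[[f]])))
    }, logical(1))
    if (any(bad))
      msg <- c(msg, "contributors: per-feature contributor scores must sum to the total")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' RunManifest: provenance record of an end-to-end run
#'
#' @slot config the configuration list the run used (after defaults).
#' @slot seeds integer random states used.
#' @slot outputs named character: stage -> output path(s).
#' @slot digests named character: md5 of every output file.
#' @slot versions named character: package/R versions.
#' @slot timestamps POSIXct start/end.
#' @aliases RunManifest-class
#' @exportClass RunManifest
setClass("RunManifest",
  representation(config = "list", seeds = "integer", outputs = "character",
                 digests = "character", versions = "character",
                 timestamps = "POSIXct"))
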