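#' @include experiment.R
NULL

#' Extract a model's feature-importance vector
#'
#' Lasso contributes the elementwise absolute values of its coefficients;
#' the tree ensembles contribute their library-native importance (impurity
#' decrease for random forest, gain for the gradient-boosting families,
#' weighted impurity importance for AdaBoost.R2). The neural network has no
#' importance and is rejected.
#'
#' @param run A \linkS4class{ModelRun}.
#' @return Named nonnegative numeric aligned to the run's feature set.
#' @export
extractImportance <- function(run) {
  if (run@algorithm == "dnn")
    stop("unsupported algorithm 'dnn': no importance vector is defined")
  if (!length(run@importance))
    stop(sprintf("run %s carries no importance vector", modelId(run)))
  run@importance
}

#' Rank-to-score mapping of one importance vector
#'
#' Features are sorted by importance (decreasing; ties broken stably by
#' feature name). The top 10 features with strictly positive importance get
#' scores 10, 9, ..., 1 by rank; every other feature scores 0. With fewer
#' than 10 positive-importance features only those are scored — a score must
#' witness signal.
#'
#' @param importance named numeric of nonnegative importances.
#' @return Named integer scores, same names and order as \code{importance}.
#' @examples
#' scoreRanking(c(a = 3, b = 5, c = 0.1, d = 0))  # b=10, a=9, c=8, d=0
#' @export
scoreRanking <- function(importance) {
  if (is.null(names(importance)))
    .validation_error("importance: must be named", field = "importance")
  if (any(importance < 0))
    .validation_error("importance: values must be >= 0", field = "importance")
  ord <- order(-importance, names(importance))
  scores <- stats::setNames(integer(length(importance)), names(importance))
  ranked <- ord[importance[ord] > 0]
  top <- utils::head(ranked, 10L)
  if (length(top)) scores[top] <- 11L - seq_along(top)
  scores
}

#' Consensus feature-importance ranking
#'
#' Eligible runs are those with test R^2 >= 0 from importance-capable
#' algorithms (everything but the neural network). Each eligible run's
#' importance vector is converted to rank scores (\code{\link{scoreRanking}})
#' and the scores are summed per feature across runs. Descriptor-set and
#' fingerprint-set runs can be consensed separately or together via
#' \code{featureSet}.
#'
#' @param runs list of \linkS4class{ModelRun}s.
#' @param featureSet \code{"descriptor"}, \code{"fingerprint"} or
#'   \code{"combined"} (default) to select which runs contribute.
#' @return A \linkS4class{ConsensusRanking}. With zero eligible runs, an
#'   empty ranking is returned with a warning (not an error).
#' @export
buildConsensus <- function(runs, featureSet = c("combined", "descriptor",
                                                "fingerprint")) {
  featureSet <- match.arg(featureSet)
  if (!length(runs)) .validation_error("runs: need at least one ModelRun",
                                       field = "runs")
  eligible <- Filter(function(r) {
    r@algorithm %in% .IMPORTANCE_ALGORITHMS && length(r@importance) &&
      !is.na(r@r2) && r@r2 >= 0 &&
      (featureSet == "combined" || r@featureSet == featureSet)
  }, runs)
  if (!length(eligible)) {
    warning("no eligible runs (test R^2 >= 0, importance-capable); empty consensus")
    return(methods::new("ConsensusRanking", scores = numeric(),
                        contributors = list(), eligibleModels = character()))
  }
  totals <- numeric()
  contributors <- list()
  for (run in eligible) {
    sc <- scoreRanking(extractImportance(run))
    sc <- sc[sc > 0]
    for (f in names(sc)) {
      totals[f] <- (if (f %in% names(totals)) totals[[f]] else 0) + sc[[f]]
      contributors[[f]] <- rbind(
        contributors[[f]],
        data.frame(model = modelId(run), rank = 11L - sc[[f]],
                   score = sc[[f]], stringsAsFactors = FALSE))
    }
  }
  ord <- order(-totals, names(totals))
  methods::new("ConsensusRanking", scores = totals[ord],
               contributors = contributors[names(totals)[ord]],
               eligibleModels = vapply(eligible, modelId, character(1)))
}

setMethod("show", "ConsensusRanking", function(object) {
  cat(sprintf("ConsensusRanking: %d scored features over %d eligible models\n",
              length(object@scores), length(object@eligibleModels)))
  if (length(object@scores)) {
    top <- utils::head(object@scores, 7L)
    cat(paste(sprintf("  %-20s %d", names(top), top), collapse = "\n"), "\n")
  }
})

#' @rdname consensusScores
#' @param x A \linkS4class{ConsensusRanking}.
#' @return Named numeric of summed scores, decreasing.
#' @export
setMethod("consensusScores", "ConsensusRanking", function(x) x@scores)

#' @describeIn buildConsensus Model ids that contributed to the consensus.
#' @param x A \linkS4class{ConsensusRanking}.
#' @export
eligibleModels <- function(x) x@eligibleModels

#' Top-k consensus features
#'
#' @param x A \linkS4class{ConsensusRanking}.
#' @param k number of rows (fewer are returned when fewer features have a
#'   positive score; no padding).
#' @param ... unused.
#' @return data.frame with columns feature, score, n_models, in
#'   non-increasing score order.
#' @rdname topFeatures
#' @export
setMethod("topFeatures", "ConsensusRanking", function(x, k = 7L, ...) {
  k <- .assert_count(k, "k", min = 1L)
  top <- utils::head(x@scores, k)
  data.frame(feature = names(top), score = unname(top),
             n_models = vapply(names(top),
                               function(f) nrow(x@contributors[[f]]), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
})

#' Serialize a consensus ranking as delimited text
#'
#' One row per scored feature with its total and the per-model
#' contributions collapsed to \code{"model:score"} pairs.
#'
#' @param x A \linkS4class{ConsensusRanking}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeConsensus <- function(x, path) {
  df <- data.frame(
    feature = names(x@scores), score = unname(x@scores),
    contributors = vapply(names(x@scores), function(f) {
      ct <- x@contributors[[f]]
      paste(sprintf("%s:%d", ct$model, ct$score), collapse = ";")
    }, character(1)), stringsAsFactors = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
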