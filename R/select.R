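#' @include AllClasses.R FeatureTable.R
NULL

.empty_removed <- function() {
  data.frame(feature = character(), stage = character(), partner = character(),
             abs_r = numeric(), stringsAsFactors = FALSE)
}

.selection_report <- function(removed, kept, threshold = NA_real_) {
  methods::new("SelectionReport", removed = removed, kept = kept,
               threshold = threshold)
}

setMethod("show", "SelectionReport", function(object) {
  tab <- table(factor(object@removed$stage,
                      levels = c("zero_variance", "duplicate", "correlation")))
  cat(sprintf(paste0("SelectionReport: kept %d, removed %d ",
                     "(zero_variance %d, duplicate %d, correlation %d)"),
              length(object@kept), nrow(object@removed),
              tab[["zero_variance"]], tab[["duplicate"]], tab[["correlation"]]))
  if (!is.na(object@threshold))
    cat(sprintf("; |r| threshold %.3g", object@threshold))
  cat("\n")
})

#' @rdname keptFeatures
#' @param x A \linkS4class{SelectionReport}.
#' @return \code{keptFeatures}: surviving feature names;
#'   \code{removedFeatures}: the removal log data.frame.
#' @export
setMethod("keptFeatures", "SelectionReport", function(x) x@kept)

#' @rdname removedFeatures
#' @param x A \linkS4class{SelectionReport}.
#' @export
setMethod("removedFeatures", "SelectionReport", function(x) x@removed)

#' Serialize a SelectionReport as delimited text
#'
#' @param x A \linkS4class{SelectionReport}.
#' @param path output CSV path; kept features go to \code{<path>.kept.csv}.
#' @return \code{path}, invisibly.
#' @export
writeSelectionReport <- function(x, path) {
  utils::write.csv(x@removed, path, row.names = FALSE)
  utils::write.csv(data.frame(feature = x@kept, threshold = x@threshold),
                   paste0(path, ".kept.csv"), row.names = FALSE)
  invisible(path)
}

#' Descriptor pruning: zero variance, duplicates, pairwise correlation
#'
#' The three pruning stages applied to a descriptor table before modelling,
#' each returning the reduced \linkS4class{FeatureTable} and a
#' \linkS4class{SelectionReport} logging every removal:
#' \describe{
#'   \item{\code{dropZeroVariance}}{removes features constant across
#'     samples.}
#'   \item{\code{dropDuplicates}}{removes features whose value vector is
#'     identical to an earlier one; the survivor of a duplicate group is the
#'     first feature in name order.}
#'   \item{\code{correlationPrune}}{iteratively, while any pair has
#'     |Pearson r| >= \code{threshold}: take the pair attaining the maximum
#'     |r|; delete the member with more partners at |r| >= threshold (ties:
#'     larger mean |r| against all other features, then the later name);
#'     recompute and repeat. The output certifies max pairwise |r| <
#'     threshold.}
#' }
#' \code{selectFeatures} composes the three stages in that order into a
#' single merged report. Fingerprint-bit features are exempt from the
#' correlation stage (the protocol prunes descriptors only and keeps the
#' full fingerprint).
#'
#' @param table A \linkS4class{FeatureTable} with >= 2 samples.
#' @param threshold correlation cutoff in (0, 1]; no default in
#'   \code{selectFeatures} configs — it must be stated explicitly to be
#'   reproducible. Default 0.95 here.
#' @return List with \code{table} (pruned \linkS4class{FeatureTable}) and
#'   \code{report} (\linkS4class{SelectionReport}).
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, 1, 1, 1))
#' rownames(m) <- paste0("s", 1:4)
#' ft <- featureTable(m)
#' selectFeatures(ft, threshold = 0.95)$report
#' @name feature-selection
NULL

#' @rdname feature-selection
#' @export
dropZeroVariance <- function(table) {
  x <- featureMatrix(table)
  if (nrow(x) < 2L)
    .validation_error("table: need at least 2 samples", field = "table")
  v <- apply(x, 2L, function(col) max(col) - min(col))
  drop <- colnames(x)[v == 0]
  if (length(drop) == ncol(x))
    warning("all features have zero variance; empty table returned")
  removed <- .empty_removed()
  if (length(drop))
    removed <- data.frame(feature = drop, stage = "zero_variance",
                          partner = NA_character_, abs_r = NA_real_,
                          stringsAsFactors = FALSE)
  kept <- setdiff(colnames(x), drop)
  list(table = .ft_keep_features(table, kept),
       report = .selection_report(removed, kept))
}

#' @rdname feature-selection
#' @export
dropDuplicates <- function(table) {
  x <- featureMatrix(table)
  if (nrow(x) < 2L)
    .validation_error("table: need at least 2 samples", field = "table")
  ord <- order(colnames(x))  # survivor = first in name order
  key <- apply(x[, ord, drop = FALSE], 2L, paste, collapse = "\r")
  dup <- duplicated(key)
  drop_nm <- colnames(x)[ord][dup]
  partner <- colnames(x)[ord][match(key[dup], key)]
  removed <- .empty_removed()
  if (length(drop_nm))
    removed <- data.frame(feature = drop_nm, stage = "duplicate",
                          partner = partner, abs_r = NA_real_,
                          stringsAsFactors = FALSE)
  kept <- setdiff(colnames(x), drop_nm)
  list(table = .ft_keep_features(table, kept),
       report = .selection_report(removed, kept))
}

## One greedy elimination pass over a correlation matrix; full recomputation
## each iteration (p is small; transparency over speed, and the greedy path
## is itself part of the contract).
.correlation_prune_matrix <- function(x, threshold) {
  removed <- .empty_removed()
  repeat {
    p <- ncol(x)
    if (p < 2L) break
    r <- abs(stats::cor(x))
    diag(r) <- 0
    mx <- max(r)
    if (mx < threshold) break
    ## pair attaining the maximum; deterministic scan order (column-major,
    ## names in current table order)
    hit <- which(r == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    pair <- hit[order(hit[, 1], hit[, 2])[1], ]
    cand <- colnames(x)[c(pair[[1]], pair[[2]])]
    ## delete the member with more partners at |r| >= threshold;
    ## ties: larger mean |r| over all other features; then later name order
    n_part <- colSums(r[, cand, drop = FALSE] >= threshold)
    mean_r <- colSums(r[, cand, drop = FALSE]) / (p - 1)
    pick <- if (n_part[1] != n_part[2]) which.max(n_part)
            else if (abs(mean_r[1] - mean_r[2]) > 1e-15) which.max(mean_r)
            else which.max(rank(cand))
    victim <- cand[pick]
    partner <- cand[3 - pick]
    removed[nrow(removed) + 1L, ] <- list(victim, "correlation", partner, mx)
    x <- x[, setdiff(colnames(x), victim), drop = FALSE]
  }
  list(x = x, removed = removed)
}

#' @rdname feature-selection
#' @export
correlationPrune <- function(table, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    .validation_error("threshold: must lie in (0, 1]", field = "threshold")
  x <- featureMatrix(table)
  v <- apply(x, 2L, function(col) max(col) - min(col))
  if (any(v == 0))
    .validation_error(paste0(
      "table: zero-variance feature(s) present (",
      paste(colnames(x)[v == 0], collapse = ", "),
      "); run dropZeroVariance first"), field = "table")
  res <- .correlation_prune_matrix(x, threshold)
  kept <- colnames(res$x)
  list(table = .ft_keep_features(table, kept),
       report = .selection_report(res$removed, kept, threshold))
}

#' @rdname feature-selection
#' @export
selectFeatures <- function(table, threshold = 0.95) {
  s1 <- dropZeroVariance(table)
  s2 <- dropDuplicates(s1$table)
  kind <- featureKind(s2$table)
  desc <- names(kind)[kind == "descriptor"]
  fp <- names(kind)[kind == "fingerprint_bit"]
  if (length(desc) >= 2L) {
    s3 <- correlationPrune(.ft_keep_features(s2$table, desc), threshold)
    kept <- c(keptFeatures(s3$report), fp)
    removed3 <- removedFeatures(s3$report)
  } else {
    kept <- c(desc, fp)
    removed3 <- .empty_removed()
  }
  ## preserve original table order among survivors
  kept <- intersect(rownames(table), kept)
  removed <- rbind(removedFeatures(s1$report), removedFeatures(s2$report),
                   removed3)
  list(table = .ft_keep_features(table, kept),
       report = .selection_report(removed, kept, threshold))
}
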