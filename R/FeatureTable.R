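#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FeatureTable
#'
#' @param values numeric matrix, samples x features, with row names (sample
#'   ids) and column names (feature names). Fingerprint columns must be 0/1.
#' @param kind character vector (length 1 or ncol(values)) of feature kinds,
#'   \code{"descriptor"} or \code{"fingerprint_bit"}.
#' @return A \linkS4class{FeatureTable}.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("desc_000", 1:3)))
#' ft <- featureTable(m, kind = "descriptor")
#' dim(ft)
#' @export
featureTable <- function(values, kind = "descriptor") {
  if (!is.matrix(values) || !is.numeric(values))
    .validation_error("values: must be a numeric matrix", field = "values")
  if (is.null(colnames(values)))
    .validation_error("values: feature (column) names are required",
                      field = "feature names")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("sample_%04d", seq_len(nrow(values)))
  kind <- rep_len(as.character(kind), ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(X = t(values)),
    rowData = S4Vectors::DataFrame(kind = kind, row.names = colnames(values)))
  methods::new("FeatureTable", se)
}

#' Feature matrix of a FeatureTable
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Numeric matrix, samples x features.
#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureTable",
          function(x) t(SummarizedExperiment::assay(x, "X")))

#' Per-feature kind tags
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Named character vector, one of \code{"descriptor"} /
#'   \code{"fingerprint_bit"} per feature.
#' @rdname featureKind
#' @export
setMethod("featureKind", "FeatureTable", function(x) {
  k <- SummarizedExperiment::rowData(x)$kind
  names(k) <- rownames(x)
  k
})

#' Sample identifiers
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Character vector of sample ids, in table order.
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "FeatureTable", function(x) colnames(x))

setMethod("show", "FeatureTable", function(object) {
  k <- table(factor(SummarizedExperiment::rowData(object)$kind,
                    levels = .FEATURE_KINDS))
  cat(sprintf("FeatureTable: %d samples x %d features (%d descriptor, %d fingerprint_bit)\n",
              ncol(object), nrow(object), k[["descriptor"]],
              k[["fingerprint_bit"]]))
})

## keep: character vector of feature names to retain (in current table order)
.ft_keep_features <- function(x, keep) x[match(keep, rownames(x)), ]

#' Stack two FeatureTables over the same samples
#'
#' Binds the feature sets of two tables (e.g. descriptors and fingerprint
#' bits) that describe the same samples in the same order.
#'
#' @param x,y \linkS4class{FeatureTable}s with identical sample ids.
#' @return A \linkS4class{FeatureTable} containing both feature sets.
#' @export
bindFeatureTables <- function(x, y) {
  if (!identical(sampleIds(x), sampleIds(y)))
    .validation_error("sample ids: tables must share identical sample order",
                      field = "sample ids")
  featureTable(cbind(featureMatrix(x), featureMatrix(y)),
               kind = c(featureKind(x), featureKind(y)))
}

#' Write / read a FeatureTable as delimited text
#'
#' The table is written samples x features as CSV with a one-line header and
#' a leading \code{sample_id} column; feature kinds go to a sidecar
#' \code{<path>.kinds.csv}. \code{readFeatureTable} restores both; if the
#' sidecar is missing, kinds are inferred from the \code{desc_}/\code{fp_}
#' name prefixes.
#'
#' @param x A \linkS4class{FeatureTable}.
#' @param path CSV file path.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns a \linkS4class{FeatureTable}.
#' @export
writeFeatureTable <- function(x, path) {
  m <- featureMatrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(x), kind = unname(featureKind(x))),
                   paste0(path, ".kinds.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    .validation_error("missing required column 'sample_id'", field = "sample_id")
  m <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  kfile <- paste0(path, ".kinds.csv")
  if (file.exists(kfile)) {
    kd <- utils::read.csv(kfile)
    kind <- kd$kind[match(colnames(m), kd$feature)]
  } else {
    kind <- ifelse(startsWith(colnames(m), "fp_"), "fingerprint_bit", "descriptor")
  }
  featureTable(m, kind = kind)
}
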