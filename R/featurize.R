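#' @include backends.R fingerprint.R FeatureTable.R
NULL

#' Build descriptor and fingerprint feature tables
#'
#' Featurizes a list of compounds into the two explanatory-variable sets the
#' pipeline models separately: a molecular-descriptor table (quantum scalars
#' plus the 2-D panel) and a Morgan-fingerprint bit table. A compound whose
#' featurization fails at any stage is dropped from \emph{both} tables
#' (never imputed) and logged in the rejection report; row order is
#' identical across both tables and the target vector.
#'
#' @param records list of \linkS4class{CompoundRecord}s (length >= 3).
#' @param backend A \linkS4class{DescriptorBackend}; default stub.
#' @param radius,nBits Morgan fingerprint parameters (default 2 / 2048).
#' @return List with \code{descriptors} and \code{fingerprints}
#'   (\linkS4class{FeatureTable}s with identical sample order), \code{y}
#'   (named target vector) and \code{rejected} (data.frame id, stage,
#'   reason).
#' @export
buildFeatureTables <- function(records, backend = descriptorBackend("stub"),
                               radius = 2L, nBits = 2048L) {
  if (length(records) < 3L)
    .validation_error("records: need at least 3 compounds", field = "records")
  ids <- vapply(records, function(r) r@id, character(1))
  if (anyDuplicated(ids))
    .validation_error("records: duplicated compound ids", field = "records")

  rejected <- data.frame(id = character(), stage = character(),
                         reason = character(), stringsAsFactors = FALSE)
  desc_rows <- list(); fp_rows <- list(); y <- numeric()
  for (rec in records) {
    d <- tryCatch(computeDescriptors(rec, backend), error = function(e) e)
    if (inherits(d, "soacqspr_capability_error")) stop(d)
    if (inherits(d, "error")) {
      rejected[nrow(rejected) + 1L, ] <- list(rec@id, "descriptors",
                                              conditionMessage(d))
      next
    }
    f <- tryCatch(computeFingerprint(rec, radius = radius, nBits = nBits),
                  error = function(e) e)
    if (inherits(f, "soacqspr_capability_error")) stop(f)
    if (inherits(f, "error")) {
      rejected[nrow(rejected) + 1L, ] <- list(rec@id, "fingerprint",
                                              conditionMessage(f))
      next
    }
    desc_rows[[rec@id]] <- descriptorVector(d)
    fp_rows[[rec@id]] <- f
    y[rec@id] <- rec@y
  }
  if (!length(desc_rows))
    .validation_error("records: featurization failed for every compound",
                      field = "records")
  desc <- do.call(rbind, desc_rows)
  fp <- do.call(rbind, fp_rows)
  list(descriptors = featureTable(desc, kind = "descriptor"),
       fingerprints = featureTable(fp, kind = "fingerprint_bit"),
       y = y, rejected = rejected)
}
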