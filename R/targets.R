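#' @include AllClasses.R
NULL

#' Modelling target: log rate ratio
#'
#' The modelling target is the natural logarithm of the ratio of a
#' compound's singlet-oxygen quenching rate constant to that of the
#' reference antioxidant (alpha-tocopherol). SOAC values are that ratio
#' already, so \code{targetFromSoac(soac) = log(soac)} and the two routes
#' agree exactly whenever \code{soac = kQ/kRef}. The reference compound
#' itself maps to 0.
#'
#' @param kQ quenching rate constant of the compound, 1/(M s); must be > 0.
#' @param kRef quenching rate constant of the reference, 1/(M s); must be > 0.
#' @return \code{log(kQ / kRef)} (dimensionless).
#' @examples
#' computeTarget(2.3e9, 2.3e7)   # log(100)
#' targetFromSoac(1)             # reference compound -> 0
#' @export
computeTarget <- function(kQ, kRef) {
  if (!all(is.finite(kQ)) || any(kQ <= 0))
    .validation_error("kQ: rate constant must be finite and > 0", field = "kQ")
  if (!all(is.finite(kRef)) || any(kRef <= 0))
    .validation_error("kRef: rate constant must be finite and > 0", field = "kRef")
  log(kQ / kRef)
}

#' @rdname computeTarget
#' @param soac SOAC value (dimensionless rate ratio); must be > 0.
#' @export
targetFromSoac <- function(soac) {
  if (!all(is.finite(soac)) || any(soac <= 0))
    .validation_error("soac: SOAC value must be finite and > 0", field = "soac")
  log(soac)
}

#' Construct a CompoundRecord
#'
#' @param id,name,smiles identifiers and isomeric SMILES.
#' @param kQ,soac rate data; at least one must be given. When both are
#'   present, \code{soac} takes precedence for the target.
#' @param kRef reference rate constant, required when only \code{kQ} is given.
#' @return A \linkS4class{CompoundRecord} with \code{y} populated.
#' @export
compoundRecord <- function(id, smiles, name = "", kQ = NA_real_,
                           soac = NA_real_, kRef = NA_real_) {
  y <- if (!is.na(soac)) targetFromSoac(soac)
       else if (!is.na(kQ)) {
         if (is.na(kRef))
           .validation_error("kRef: required when the target comes from kQ",
                             field = "kRef")
         computeTarget(kQ, kRef)
       } else .validation_error("kQ/soac: at least one must be present",
                                field = "kQ/soac")
  methods::new("CompoundRecord", id = as.character(id),
               name = as.character(name), smiles = as.character(smiles),
               kQ = as.numeric(kQ), soac = as.numeric(soac), y = y)
}

setMethod("show", "CompoundRecord", function(object) {
  cat(sprintf("CompoundRecord %s (%s): y = %.4g, smiles = %s\n", object@id,
              object@name, object@y, object@smiles))
})

#' Read a compound table
#'
#' Reads a delimited text file with a header naming at least \code{id} and
#' \code{smiles}, plus a target source: a \code{soac} column and/or a
#' \code{k_q} column (the latter requires \code{kRef}). When both are
#' present, \code{soac} takes precedence. Rows with unusable values
#' (non-numeric or non-positive rate data, missing/empty SMILES) are
#' collected into a rejection report and the run continues.
#'
#' @param path CSV/TSV file (delimiter sniffed from the header line).
#' @param kRef reference quenching rate constant (1/(M s)), needed when the
#'   target is derived from \code{k_q}.
#' @return List with \code{records} (list of \linkS4class{CompoundRecord})
#'   and \code{rejected} (data.frame with columns id, row, reason).
#' @export
readCompounds <- function(path, kRef = NA_real_) {
  if (!file.exists(path))
    .validation_error(sprintf("file not found: %s", path), field = "path")
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = TRUE, quote = "\"", comment.char = "")
  cols <- tolower(colnames(df))
  colnames(df) <- cols
  for (required in c("id", "smiles"))
    if (!required %in% cols)
      .validation_error(sprintf("missing required column '%s'", required),
                        field = required)
  has_soac <- "soac" %in% cols
  has_kq <- "k_q" %in% cols
  if (!has_soac && !has_kq)
    .validation_error("missing target column: need 'soac' or 'k_q'",
                      field = "soac/k_q")
  if (!has_soac && is.na(kRef))
    .validation_error("kRef: must be supplied when only 'k_q' is present",
                      field = "kRef")

  records <- list()
  rejected <- data.frame(id = character(), row = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  reject <- function(i, reason) {
    rejected[nrow(rejected) + 1L, ] <<- list(df$id[i], i, reason)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nrow(df))) {
    smi <- df$smiles[i]
    if (is.na(smi) || !nzchar(trimws(smi))) { reject(i, "missing SMILES"); next }
    soac <- if (has_soac) num(df$soac[i]) else NA_real_
    kq <- if (has_kq) num(df$k_q[i]) else NA_real_
    if (has_soac && !is.na(df$soac[i]) && nzchar(df$soac[i]) && is.na(soac)) {
      reject(i, sprintf("soac not numeric: '%s'", df$soac[i])); next
    }
    rec <- tryCatch(
      compoundRecord(id = df$id[i], smiles = trimws(smi),
                     name = if ("name" %in% cols) df$name[i] else "",
                     kQ = kq, soac = soac, kRef = kRef),
      error = function(e) e)
    if (inherits(rec, "error")) reject(i, conditionMessage(rec))
    else records[[length(records) + 1L]] <- rec
  }
  list(records = records, rejected = rejected)
}
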