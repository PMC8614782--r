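## Internal helpers: error conditions, seeded RNG streams, string hashing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.validation_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("soacqspr_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

#' @noRd
.capability_error <- function(msg, backend = NULL) {
  stop(structure(
    class = c("soacqspr_capability_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), backend = backend)
  ))
}

## 32-bit FNV-1a over UTF-8 bytes, folded to a non-negative value < 2^31
## so it is always a legal set.seed() argument.
.hash32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  m <- 16777619
  h <- 2166136261 %% 2^31
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    ## exact (h * m) mod 2^31 in doubles: split h to stay below 2^53
    h1 <- h %/% 2^16
    h0 <- h %% 2^16
    h <- (((h1 * m) %% 2^31) * 2^16 + h0 * m) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

## One RNG stream per (seed, operation tag): derived seeds never collide with
## the raw user seed and adding new tagged operations cannot shift existing
## streams. Restores the caller's RNG state on exit.
.with_op_seed <- function(seed, tag, expr) {
  derived <- (as.numeric(seed) + .hash32(tag)) %% .Machine$integer.max
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  expr
}

.assert_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .validation_error(sprintf("'%s' must be a single integer >= %d", field, min),
                      field = field)
  invisible(as.integer(x))
}

.log_stage <- function(stage, ..., con = NULL) {
  msg <- sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste0(..., collapse = " "))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(msg)
}
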