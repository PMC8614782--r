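## Independent brute-force oracles. These deliberately share no code with the
## package implementations: plain loops, full recomputation at every step.

## Greedy correlation pruning, recomputing the full correlation matrix with
## explicit pairwise loops at each iteration. Returns the removal sequence.
oracle_corr_prune <- function(x, threshold) {
  removed <- character()
  repeat {
    p <- ncol(x)
    if (p < 2) break
    best <- c(NA, NA); best_r <- -1
    for (i in seq_len(p - 1)) {
      for (j in seq(i + 1, p)) {
        r <- abs(cor(x[, i], x[, j]))
        if (r > best_r + 1e-15) { best_r <- r; best <- c(i, j) }
      }
    }
    if (best_r < threshold) break
    cand <- colnames(x)[best]
    n_part <- numeric(2); mean_r <- numeric(2)
    for (k in 1:2) {
      rs <- sapply(setdiff(seq_len(p), best[k]),
                   function(j) abs(cor(x[, best[k]], x[, j])))
      n_part[k] <- sum(rs >= threshold)
      mean_r[k] <- mean(rs)
    }
    pick <- if (n_part[1] != n_part[2]) which.max(n_part)
            else if (abs(mean_r[1] - mean_r[2]) > 1e-15) which.max(mean_r)
            else which(cand == sort(cand)[2])  # later name is deleted
    removed <- c(removed, cand[pick])
    x <- x[, -best[pick], drop = FALSE]
  }
  removed
}

## Consensus by explicit enumeration of (model, rank) pairs.
## importances: list of named vectors; r2s: numeric vector, same length.
oracle_consensus <- function(importances, r2s) {
  totals <- list()
  for (m in seq_along(importances)) {
    if (is.na(r2s[m]) || r2s[m] < 0) next
    v <- importances[[m]]
    v <- v[v > 0]
    ord <- names(v)[order(-v, names(v))]
    for (k in seq_along(ord)) {
      if (k > 10) break
      f <- ord[k]
      totals[[f]] <- (if (is.null(totals[[f]])) 0 else totals[[f]]) + (11 - k)
    }
  }
  if (!length(totals)) return(setNames(numeric(0), character(0)))
  unlist(totals)[order(-unlist(totals), names(unlist(totals)))]
}

## fitModel-compatible custom fitters -----------------------------------------

## records every training set it sees; predicts the training mean
counting_fitter <- function(log_env) {
  function(x, y, hyperparameters, randomState) {
    log_env$fits <- c(log_env$fits %||% list(),
                      list(list(n = nrow(x), ids = rownames(x))))
    mu <- mean(y)
    list(predict = function(newx) rep(mu, nrow(newx)), importance = NULL)
  }
}

## 1-nearest-neighbour regressor (Euclidean)
onenn_fitter <- function(x, y, hyperparameters, randomState) {
  list(predict = function(newx) {
    apply(newx, 1, function(row) {
      d <- sqrt(colSums((t(x) - row)^2))
      y[which.min(d)]
    })
  }, importance = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
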