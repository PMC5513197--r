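# exhaustive oracle: per size, the best-RSS subset over the full universe;
# size chosen by the same fold-wise rule as the search (per-fold exhaustive
# best subsets scored out of fold), then the full-data best of that size
exhaustive_best_per_size <- function(X, y, maxsize) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  best <- list(integer(0))
  for (k in seq_len(maxsize)) {
    combs <- utils::combn(ncol(X), k)
    rss <- apply(combs, 2, function(idx)
      exposelect:::rss_of_set(Xc, yc, idx, sum(yc^2)))
    best[[k + 1L]] <- combs[, which.min(rss)]
  }
  best
}

exhaustive_best_by_cv <- function(data, outcome, config) {
  d <- exposelect:::split_exposures(data, outcome)
  E <- d$E; y <- d$y
  n <- length(y)
  universe <- exposelect:::dsa_universe(ncol(E), config$maxorder)
  X <- design_columns(E, universe)
  best <- exhaustive_best_per_size(X, y, config$maxsize)
  fold_id <- exposelect:::with_seed(config$seed,
    sample(rep(seq_len(config$folds), length.out = n)))
  sq_err <- matrix(NA_real_, n, config$maxsize + 1L)
  for (f in seq_len(config$folds)) {
    te <- fold_id == f
    best_f <- exhaustive_best_per_size(X[!te, , drop = FALSE], y[!te],
                                       config$maxsize)
    for (k in 0:config$maxsize) {
      idx_f <- best_f[[k + 1L]]
      pred <- exposelect:::ols_predict(cbind(1, X[!te, idx_f, drop = FALSE]),
                                       y[!te],
                                       cbind(1, X[te, idx_f, drop = FALSE]))
      sq_err[te, k + 1L] <- (y[te] - pred)^2
    }
  }
  cv <- sqrt(colMeans(sq_err))
  idx <- best[[which.min(cv)]]
  exposelect:::term_labels(universe[idx, , drop = FALSE])
}

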