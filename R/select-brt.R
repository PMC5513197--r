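#' Configuration for boosted regression trees with variable elimination
#'
#' @param max_trees Maximum boosting iterations.
#' @param depth Tree depth (interpretable as the maximum interaction
#'   order captured).
#' @param learning_rate Shrinkage per boosting step.
#' @param bag_fraction Row subsample fraction per tree.
#' @param elimination_fraction Fraction `f` of variables dropped (lowest
#'   importance) at each backward-elimination step.
#' @param holdout_fraction Fraction of rows held out for the out-of-sample
#'   error that picks the number of trees and the final variable set.
#' @param seed Integer seed.
#' @return A list of class `brt_config`.
#' @export
brt_config <- function(max_trees = 5000L, depth = 4L, learning_rate = 0.01,
                       bag_fraction = 0.5, elimination_fraction = 0.5,
                       holdout_fraction = 0.25, seed = 1L) {
  stopifnot(depth >= 1, learning_rate > 0, elimination_fraction > 0,
            elimination_fraction < 1, holdout_fraction > 0,
            holdout_fraction < 1)
  structure(list(max_trees = as.integer(max_trees),
                 depth = as.integer(depth), learning_rate = learning_rate,
                 bag_fraction = bag_fraction,
                 elimination_fraction = elimination_fraction,
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "brt_config")
}

# split-gain importance per feature: total squared improvement of all
# splits on the feature, averaged over trees
brt_importance <- function(booster, feature_names, n_trees) {
  imp <- stats::setNames(rep(0, length(feature_names)), feature_names)
  tr <- tryCatch(xgboost::xgb.model.dt.tree(model = booster),
                 error = function(e) NULL)
  if (!is.null(tr)) {
    tr <- as.data.frame(tr)
    splits <- tr[tr$Feature != "Leaf" & tr$Tree < n_trees, , drop = FALSE]
    if (nrow(splits) > 0) {
      agg <- tapply(splits$Gain, splits$Feature, sum)
      imp[names(agg)] <- agg / max(n_trees, 1L)
    }
  }
  imp
}

#' Fit a boosted regression tree ensemble
#'
#' Stage-wise squared-error gradient boosting with shrinkage and row
#' subsampling. The number of trees is the minimizer of the error on a
#' seeded holdout fraction (at most `max_trees`). Importance of a variable
#' is the total squared improvement of its splits averaged over trees.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param config A [brt_config()].
#' @param holdout_id Optional logical vector marking holdout rows (used by
#'   the elimination wrapper so every fit shares one holdout).
#' @return A list with `booster`, `importance` (tibble: variable, index,
#'   importance), `holdout_error` (MSE at the chosen iteration),
#'   `best_iter`, `predict_fn`.
#' @export
fit_brt <- function(data, outcome = "y", config = brt_config(),
                    holdout_id = NULL) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  n <- nrow(E)
  if (n < 50) {
    stop_exposelect("need at least 50 observations.",
                    "exposelect_fit_error")
  }
  if (is.null(holdout_id)) {
    holdout_id <- with_seed(derive_seed(config$seed, "holdout"), {
      id <- rep(FALSE, n)
      id[sample(n, max(1, round(config$holdout_fraction * n)))] <- TRUE
      id
    })
  }
  imp0 <- tibble::tibble(variable = colnames(E),
                         index = seq_len(ncol(E)), importance = 0)
  if (stats::var(y) < 1e-24) {
    mu <- mean(y)
    return(list(booster = NULL, importance = imp0,
                holdout_error = 0, best_iter = 0L,
                predict_fn = function(Enew) rep(mu, nrow(as.matrix(Enew)))))
  }
  dtr <- xgboost::xgb.DMatrix(E[!holdout_id, , drop = FALSE],
                              label = y[!holdout_id])
  dte <- xgboost::xgb.DMatrix(E[holdout_id, , drop = FALSE],
                              label = y[holdout_id])
  booster <- with_seed(config$seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror",
                  eta = config$learning_rate, max_depth = config$depth,
                  subsample = config$bag_fraction, nthread = 1,
                  seed = config$seed, base_score = mean(y[!holdout_id])),
    data = dtr, nrounds = config$max_trees,
    evals = list(holdout = dte), verbose = 0,
    early_stopping_rounds = 50L))
  log_rmse <- as.data.frame(attr(booster, "evaluation_log"))$holdout_rmse
  best_iter <- which.min(log_rmse)
  imp <- brt_importance(booster, colnames(E), best_iter)
  imp_tb <- tibble::tibble(variable = colnames(E),
                           index = seq_len(ncol(E)),
                           importance = unname(imp[colnames(E)]))
  predict_fn <- local({
    b <- booster; it <- best_iter
    function(Enew) stats::predict(b, as.matrix(Enew),
                                  iterationrange = c(1, it + 1))
  })
  list(booster = booster, importance = imp_tb,
       holdout_error = log_rmse[best_iter]^2, best_iter = best_iter,
       predict_fn = predict_fn)
}

#' Backward variable elimination around boosted regression trees
#'
#' Iteratively fits the ensemble, records the out-of-sample (holdout) error
#' of the current variable set, and drops the fraction `f` of variables
#' with the smallest importance (at least one) until a single variable
#' remains; equivalently, each step retains `ceiling((1 - f) p)` variables.
#' The returned set is the smallest recorded set whose holdout error equals
#' the minimum over all recorded sets. Selected variables are recorded as
#' main terms for bookkeeping only: the method provides predictions, not a
#' regression equation, so term-level measures do not apply.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param config A [brt_config()].
#' @return A `selected_model` with `term_level = FALSE`.
#' @export
brt_variable_selection <- function(data, outcome = "y",
                                   config = brt_config()) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  n <- nrow(E)
  holdout_id <- with_seed(derive_seed(config$seed, "holdout"), {
    id <- rep(FALSE, n)
    id[sample(n, max(1, round(config$holdout_fraction * n)))] <- TRUE
    id
  })
  vars <- seq_len(ncol(E))
  trace <- list()
  repeat {
    sub <- data.frame(E[, vars, drop = FALSE])
    sub$.y <- y
    fit <- fit_brt(sub, outcome = ".y", config = config,
                   holdout_id = holdout_id)
    trace[[length(trace) + 1L]] <- list(vars = vars,
                                        error = fit$holdout_error,
                                        fit = fit)
    if (length(vars) == 1L) break
    keep_n <- ceiling((1 - config$elimination_fraction) * length(vars))
    keep_n <- min(keep_n, length(vars) - 1L)
    imp <- fit$importance$importance
    ord <- order(-imp, fit$importance$index)
    vars <- sort(vars[ord[seq_len(keep_n)]])
  }
  errors <- vapply(trace, function(t) t$error, numeric(1))
  sizes <- vapply(trace, function(t) length(t$vars), integer(1))
  emin <- min(errors)
  at_min <- which(errors <= emin)
  chosen <- at_min[which.min(sizes[at_min])]
  sel <- trace[[chosen]]
  terms <- purrr::map_dfr(sel$vars, term_main)
  predict_fn <- local({
    vars_ <- sel$vars; pf <- sel$fit$predict_fn
    function(Enew) pf(as.matrix(Enew)[, vars_, drop = FALSE])
  })
  selected_model("BRT", terms, has_single_model = TRUE, predicts = TRUE,
                 searches_interactions = FALSE, term_level = FALSE,
                 predict_fn = predict_fn,
                 info = list(trace = tibble::tibble(
                               step = seq_along(sizes), size = sizes,
                               holdout_error = errors),
                             chosen_size = sizes[chosen],
                             importance = sel$fit$importance))
}
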