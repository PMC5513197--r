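#' Configuration for the penalized selectors
#'
#' @param folds Cross-validation folds (3 keeps the lasso and the
#'   group-lasso interaction model comparable).
#' @param n_lambda Length of the penalty path.
#' @param lambda_min_ratio Smallest/largest penalty ratio.
#' @param tol Relative convergence tolerance of the solver.
#' @param max_iter Iteration cap per penalty value.
#' @param seed Integer seed (fold assignment).
#' @param interaction_universe `"all"` (every unordered pair) or `"none"`
#'   (mains only; the group-lasso model then reduces to the lasso).
#' @param screen_pairs With more than `screen_threshold` exposures, keep
#'   only this many candidate pairs, ranked by the absolute correlation of
#'   the product column with the outcome (sure screening); set to `Inf` to
#'   disable.
#' @param screen_threshold Exposure count above which screening activates.
#' @return A list of class `penalized_config`.
#' @export
penalized_config <- function(folds = 3L, n_lambda = 50L,
                             lambda_min_ratio = 0.01, tol = 1e-5,
                             max_iter = 20000L, seed = 1L,
                             interaction_universe = c("all", "none"),
                             screen_pairs = 5000L, screen_threshold = 100L) {
  stopifnot(folds >= 2, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1)
  structure(list(folds = as.integer(folds), n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 interaction_universe = match.arg(interaction_universe),
                 screen_pairs = screen_pairs,
                 screen_threshold = as.integer(screen_threshold)),
            class = "penalized_config")
}

seeded_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

#' Lasso selection of main effects
#'
#' Minimizes the residual sum of squares penalized by the sum of absolute
#' coefficients over a decreasing penalty path, picks the penalty with the
#' smallest mean cross-validated squared error, and returns the exposures
#' with nonzero coefficients there (on the original scale). No interaction
#' terms are searched.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param config A [penalized_config()].
#' @return A `selected_model` with penalized coefficients.
#' @export
lasso_select <- function(data, outcome = "y", config = penalized_config()) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  fold_id <- seeded_folds(length(y), config$folds, config$seed)
  cv <- glmnet::cv.glmnet(E, y, family = "gaussian", alpha = 1,
                          foldid = fold_id, nlambda = config$n_lambda,
                          lambda.min.ratio = config$lambda_min_ratio,
                          thresh = 1e-10)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  b0 <- co[1, 1]
  beta <- co[-1, 1]
  sel <- which(abs(beta) > 1e-8)
  terms <- purrr::map_dfr(sel, term_main)
  coefs <- beta[sel]
  names(coefs) <- term_labels(terms)
  predict_fn <- local({
    cvfit <- cv
    function(Enew) drop(stats::predict(cvfit, newx = as.matrix(Enew),
                                       s = "lambda.min"))
  })
  selected_model("LASSO", terms, coefficients = coefs, intercept = b0,
                 has_single_model = TRUE, predicts = TRUE,
                 searches_interactions = FALSE, term_level = TRUE,
                 predict_fn = predict_fn,
                 info = list(lambda_min = cv$lambda.min,
                             lambda = cv$lambda, cvm = cv$cvm))
}

# ---- strong-hierarchy overlapped group lasso ------------------------------

# prepare the standardized design: standardized mains, centered products
glint_design <- function(E, y, pairs) {
  n <- nrow(E)
  m <- colMeans(E)
  s <- apply(E, 2, stats::sd)
  s[s < 1e-12] <- 1
  Xs <- sweep(sweep(E, 2, m), 2, s, "/")
  q <- if (is.null(pairs)) 0L else ncol(pairs)
  if (q > 0L) {
    P <- Xs[, pairs[1, ], drop = FALSE] * Xs[, pairs[2, ], drop = FALSE]
    pm <- colMeans(P)
    P <- sweep(P, 2, pm)
  } else {
    P <- matrix(0, n, 0); pm <- numeric(0)
  }
  list(Xs = Xs, P = P, ybar = mean(y), yc = y - mean(y), m = m, s = s,
       pm = pm, pairs = pairs, n = n)
}

# per-variable main totals: alpha plus the main components of every group
# containing the variable
glint_totals <- function(alpha, theta, pairs) {
  tot <- alpha
  if (!is.null(pairs) && ncol(pairs) > 0L) {
    add <- vapply(seq_along(alpha), function(i) {
      sum(theta[1, pairs[1, ] == i]) + sum(theta[2, pairs[2, ] == i])
    }, numeric(1))
    tot <- tot + add
  }
  tot
}

glint_predict_std <- function(des, alpha, theta) {
  tot <- glint_totals(alpha, theta, des$pairs)
  out <- drop(des$Xs %*% tot)
  if (ncol(des$P) > 0L) out <- out + drop(des$P %*% theta[3, ])
  out
}

glint_objective <- function(des, alpha, theta, lambda, w) {
  r <- des$yc - glint_predict_std(des, alpha, theta)
  pen <- sum(abs(alpha))
  if (ncol(des$P) > 0L) pen <- pen + w * sum(sqrt(colSums(theta^2)))
  sum(r^2) / (2 * des$n) + lambda * pen
}

# spectral-norm bound of the implicit design (power iteration)
glint_lipschitz <- function(des, iters = 30L) {
  p <- ncol(des$Xs); q <- ncol(des$P)
  v_a <- stats::rnorm(p); v_t <- matrix(stats::rnorm(3 * max(q, 1)), 3)
  if (q == 0L) v_t <- matrix(0, 3, 0)
  nrm <- sqrt(sum(v_a^2) + sum(v_t^2))
  v_a <- v_a / nrm; if (q > 0L) v_t <- v_t / nrm
  est <- 1
  for (it in seq_len(iters)) {
    pred <- glint_predict_std(des, v_a, v_t)
    u <- drop(crossprod(des$Xs, pred))
    a_new <- u
    t_new <- if (q > 0L) {
      rbind(u[des$pairs[1, ]], u[des$pairs[2, ]],
            drop(crossprod(des$P, pred)))
    } else matrix(0, 3, 0)
    est <- sqrt(sum(a_new^2) + sum(t_new^2))
    v_a <- a_new / est
    if (q > 0L) v_t <- t_new / est
  }
  est / des$n
}

soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

group_soft <- function(Th, t) {
  if (ncol(Th) == 0L) return(Th)
  nrm <- sqrt(colSums(Th^2))
  scl <- ifelse(nrm > t, 1 - t / pmax(nrm, 1e-300), 0)
  sweep(Th, 2, scl, "*")
}

# FISTA at one penalty value, warm-started
glint_fit_one <- function(des, lambda, w, alpha, theta, L, tol, max_iter) {
  xa <- alpha; xt <- theta
  za <- alpha; zt <- theta
  tk <- 1
  obj <- glint_objective(des, xa, xt, lambda, w)
  step <- 1 / L
  q <- ncol(des$P)
  for (it in seq_len(max_iter)) {
    r <- glint_predict_std(des, za, zt) - des$yc
    u <- drop(crossprod(des$Xs, r)) / des$n
    a_new <- soft(za - step * u, step * lambda)
    if (q > 0L) {
      gt <- rbind(u[des$pairs[1, ]], u[des$pairs[2, ]],
                  drop(crossprod(des$P, r)) / des$n)
      t_new <- group_soft(zt - step * gt, step * lambda * w)
    } else t_new <- zt
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    mom <- (tk - 1) / tk_new
    za <- a_new + mom * (a_new - xa)
    if (q > 0L) zt <- t_new + mom * (t_new - xt)
    xa <- a_new; xt <- t_new; tk <- tk_new
    if (it %% 10L == 0L) {
      obj_new <- glint_objective(des, xa, xt, lambda, w)
      if (obj_new > obj) { # restart momentum
        za <- xa; zt <- xt; tk <- 1
      }
      if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
        return(list(alpha = xa, theta = xt, iters = it, converged = TRUE))
      }
      obj <- obj_new
    }
  }
  list(alpha = xa, theta = xt, iters = max_iter, converged = FALSE)
}

# full decreasing-lambda path with warm starts
glint_path <- function(des, lambda, w, tol, max_iter) {
  p <- ncol(des$Xs); q <- ncol(des$P)
  L <- glint_lipschitz(des)
  alpha <- rep(0, p); theta <- matrix(0, 3, q)
  out <- vector("list", length(lambda))
  for (k in seq_along(lambda)) {
    fit <- glint_fit_one(des, lambda[k], w, alpha, theta, L, tol, max_iter)
    if (!fit$converged) {
      stop_exposelect(sprintf("group-lasso solver did not converge at lambda index %d", k),
                      "exposelect_fit_error")
    }
    alpha <- fit$alpha; theta <- fit$theta
    out[[k]] <- fit
  }
  out
}

glint_lambda_max <- function(des, w) {
  u <- abs(drop(crossprod(des$Xs, des$yc))) / des$n
  lam <- max(u)
  q <- ncol(des$P)
  if (q > 0L) {
    v <- drop(crossprod(des$P, des$yc)) / des$n
    gn <- sqrt(u[des$pairs[1, ]]^2 + u[des$pairs[2, ]]^2 + v^2)
    lam <- max(lam, max(gn) / w)
  }
  lam
}

# candidate pair universe, optionally sure-screened by |cor(Xi*Xj, y)|
glint_pairs <- function(E, y, config) {
  p <- ncol(E)
  if (config$interaction_universe == "none" || p < 2L) return(NULL)
  pairs <- utils::combn(p, 2L)
  if (p > config$screen_threshold &&
      ncol(pairs) > config$screen_pairs) {
    sc <- abs(vapply(seq_len(ncol(pairs)), function(g) {
      suppressWarnings(stats::cor(E[, pairs[1, g]] * E[, pairs[2, g]], y))
    }, numeric(1)))
    sc[is.na(sc)] <- 0
    keep <- order(sc, decreasing = TRUE)[seq_len(config$screen_pairs)]
    pairs <- pairs[, sort(keep), drop = FALSE]
  }
  pairs
}

#' Strong-hierarchy group-lasso interaction selection
#'
#' Fits a linear pairwise-interaction model under an overlapped group
#' lasso: besides one singleton group per exposure, every candidate pair
#' (i, j) contributes a three-coefficient group (the two mains and the
#' product), penalized by its Euclidean norm with weight `sqrt(3)`. A
#' nonzero product coefficient can only occur when its whole group is
#' active, so selected interactions always come with their main effects
#' (strong hierarchy). The penalty is chosen by shared-fold cross-validation
#' over a decreasing path, and the final coefficient of a variable is the
#' sum over all groups containing it. Exposures are standardized before
#' products are formed; products are centered; reported coefficients are
#' mapped back to the original scale.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param config A [penalized_config()].
#' @return A `selected_model` with mains and interactions.
#' @export
glinternet_select <- function(data, outcome = "y",
                              config = penalized_config()) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  n <- nrow(E); p <- ncol(E)
  w <- sqrt(3)
  pairs <- glint_pairs(E, y, config)
  des <- glint_design(E, y, pairs)
  lam_max <- glint_lambda_max(des, w)
  lambda <- exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
                    length.out = config$n_lambda))

  # shared-fold cross-validation over the path
  fold_id <- seeded_folds(n, config$folds, config$seed)
  cvm <- matrix(NA_real_, config$folds, length(lambda))
  for (f in seq_len(config$folds)) {
    tr <- fold_id != f
    des_f <- glint_design(E[tr, , drop = FALSE], y[tr], pairs)
    path_f <- glint_path(des_f, lambda, w, config$tol, config$max_iter)
    Ete <- E[!tr, , drop = FALSE]
    Xs_te <- sweep(sweep(Ete, 2, des_f$m), 2, des_f$s, "/")
    P_te <- if (!is.null(pairs) && ncol(pairs) > 0L) {
      sweep(Xs_te[, pairs[1, ], drop = FALSE] *
              Xs_te[, pairs[2, ], drop = FALSE], 2, des_f$pm)
    } else matrix(0, nrow(Ete), 0)
    for (k in seq_along(lambda)) {
      tot <- glint_totals(path_f[[k]]$alpha, path_f[[k]]$theta, pairs)
      pred <- des_f$ybar + drop(Xs_te %*% tot) +
        (if (ncol(P_te) > 0L) drop(P_te %*% path_f[[k]]$theta[3, ]) else 0)
      cvm[f, k] <- mean((y[!tr] - pred)^2)
    }
  }
  cv_mean <- colMeans(cvm)
  k_star <- which.min(cv_mean)

  path <- glint_path(des, lambda[seq_len(k_star)], w, config$tol,
                     config$max_iter)
  fit <- path[[k_star]]
  alpha <- fit$alpha; theta <- fit$theta
  ztol <- 1e-8
  tot <- glint_totals(alpha, theta, pairs)
  sel_inter <- if (!is.null(pairs) && ncol(pairs) > 0L) {
    which(abs(theta[3, ]) > ztol)
  } else integer(0)
  sel_main <- sort(unique(c(which(abs(tot) > ztol),
                            if (length(sel_inter))
                              as.integer(pairs[, sel_inter]))))

  # back-transform to the original scale
  s <- des$s; m <- des$m
  coef_inter <- if (length(sel_inter)) {
    theta[3, sel_inter] / (s[pairs[1, sel_inter]] * s[pairs[2, sel_inter]])
  } else numeric(0)
  b_main <- tot / s
  if (length(sel_inter)) {
    for (k in seq_along(sel_inter)) {
      g <- sel_inter[k]
      i <- pairs[1, g]; j <- pairs[2, g]
      b_main[i] <- b_main[i] - coef_inter[k] * m[j]
      b_main[j] <- b_main[j] - coef_inter[k] * m[i]
    }
  }
  b0 <- des$ybar - sum(tot * m / s)
  if (length(sel_inter)) {
    g <- sel_inter
    b0 <- b0 + sum(coef_inter * m[pairs[1, g]] * m[pairs[2, g]]) -
      sum(theta[3, g] * des$pm[g])
  }

  terms <- NULL
  coefs <- numeric(0)
  if (length(sel_main)) {
    terms <- purrr::map_dfr(sel_main, term_main)
    coefs <- b_main[sel_main]
  }
  if (length(sel_inter)) {
    ti <- term_inter(pairs[1, sel_inter], pairs[2, sel_inter])
    terms <- dplyr::bind_rows(terms, ti)
    coefs <- c(coefs, coef_inter)
  }
  if (!is.null(terms)) names(coefs) <- term_labels(terms)

  predict_fn <- local({
    m_ <- m; s_ <- s; pm_ <- des$pm; pairs_ <- pairs
    tot_ <- tot; th3 <- if (ncol(theta) > 0L) theta[3, ] else numeric(0)
    yb <- des$ybar
    function(Enew) {
      Enew <- as.matrix(Enew)
      Xs <- sweep(sweep(Enew, 2, m_), 2, s_, "/")
      out <- yb + drop(Xs %*% tot_)
      if (!is.null(pairs_) && length(th3)) {
        P <- sweep(Xs[, pairs_[1, ], drop = FALSE] *
                     Xs[, pairs_[2, ], drop = FALSE], 2, pm_)
        out <- out + drop(P %*% th3)
      }
      out
    }
  })

  selected_model("GLINTERNET", terms, coefficients = coefs, intercept = b0,
                 has_single_model = TRUE, predicts = TRUE,
                 searches_interactions = TRUE, term_level = TRUE,
                 predict_fn = predict_fn,
                 info = list(lambda = lambda, cv_mean = cv_mean,
                             lambda_min = lambda[k_star],
                             n_pairs = if (is.null(pairs)) 0L
                                       else ncol(pairs),
                             alpha = alpha, theta = theta,
                             totals_std = tot))
}

#' Cross-validation curve for a path fitter
#'
#' Shared-fold engine: the same fold partition is reused for every penalty
#' value, errors are averaged over folds, and the index of the smallest
#' mean error is returned.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param fit_at_lambda Function `(E_train, y_train, lambda)` returning a
#'   function `(E_test)` that yields an `n_test x length(lambda)` matrix of
#'   predictions.
#' @param lambda Penalty path (any decreasing grid; can be a single 0 for
#'   unpenalized fits).
#' @param config A [penalized_config()] (folds and seed are used).
#' @return A list with `curve` (tibble: lambda, mean_error, se_error) and
#'   `lambda_min_index`.
#' @export
cv_curve <- function(data, outcome = "y", fit_at_lambda, lambda,
                     config = penalized_config()) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  n <- length(y)
  folds <- config$folds
  if (folds > n) {
    stop_exposelect("more folds than observations.",
                    "exposelect_config_error")
  }
  fold_id <- if (folds == n) seq_len(n)
             else seeded_folds(n, folds, config$seed)
  if (min(table(fold_id)) < 1L) {
    stop_exposelect("empty cross-validation fold.",
                    "exposelect_config_error")
  }
  errs <- matrix(NA_real_, folds, length(lambda))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    pred_fun <- fit_at_lambda(E[!te, , drop = FALSE], y[!te], lambda)
    pred <- pred_fun(E[te, , drop = FALSE])
    pred <- matrix(pred, nrow = sum(te))
    errs[f, ] <- colMeans((y[te] - pred)^2)
  }
  mean_error <- colMeans(errs)
  se_error <- apply(errs, 2, stats::sd) / sqrt(folds)
  list(curve = tibble::tibble(lambda = lambda, mean_error = mean_error,
                              se_error = se_error),
       lambda_min_index = which.min(mean_error))
}
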