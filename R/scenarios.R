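#' Registry of outcome-generating scenarios
#'
#' One row per subscenario. All true models involve five exposures with
#' unit main effects (beta0 = ... = beta5 = 1); scenario 1 has no
#' interaction, scenario 2 one two-way interaction (gamma12 X1 X2), and
#' scenario 3 two interactions sharing X1 (gamma12 X1 X2 + gamma13 X1 X3).
#' Subscenarios vary the target adjusted R-squared (about 0.1 or 0.3), the
#' correlation mode of the true predictors (`mixed`: drawn from the whole
#' exposome; `high`: drawn from the 13-exposure block with all pairwise
#' |r| >= 0.62; `low`: drawn from the 13-exposure block with all pairwise
#' |r| <= 0.1), and the size/sign of the interaction (strong = same size as
#' the mains, moderate = half). The residual standard deviation sigma is
#' the value tuned for each subscenario; for the low-correlation
#' sensitivity subscenario (2i) it is calibrated at run time from the
#' target R-squared via [calibrate_sigma()].
#'
#' @return A tibble with one row per subscenario.
#' @export
scenario_registry <- function() {
  tibble::tribble(
    ~scenario_id, ~scenario, ~n_interactions, ~correlation_mode,
    ~interaction_size, ~interaction_sign, ~gamma12, ~gamma13, ~sigma,
    ~target_r2,
    "1a", 1L, 0L, "mixed", "none", "none", 0, 0, 7.5, 0.10,
    "1b", 1L, 0L, "mixed", "none", "none", 0, 0, 3.8, 0.30,
    "1c", 1L, 0L, "high", "none", "none", 0, 0, 13, 0.11,
    "1d", 1L, 0L, "high", "none", "none", 0, 0, 7.5, 0.27,
    "2a", 2L, 1L, "mixed", "strong", "+", 1, 0, 8.3, 0.09,
    "2b", 2L, 1L, "mixed", "strong", "-", -1, 0, 8.3, 0.09,
    "2c", 2L, 1L, "mixed", "moderate", "+", 0.5, 0, 7.8, 0.10,
    "2d", 2L, 1L, "mixed", "moderate", "-", -0.5, 0, 7.8, 0.10,
    "2e", 2L, 1L, "high", "strong", "+", 1, 0, 12, 0.13,
    "2f", 2L, 1L, "high", "strong", "-", -1, 0, 12, 0.13,
    "2g", 2L, 1L, "high", "moderate", "+", 0.5, 0, 7, 0.30,
    "2h", 2L, 1L, "high", "moderate", "-", -0.5, 0, 7, 0.30,
    "2i", 2L, 1L, "low", "strong", "+", 1, 0, NA, 0.09,
    "3a", 3L, 2L, "mixed", "strong", "+", 1, 1, 8.3, 0.11,
    "3b", 3L, 2L, "mixed", "strong", "-", -1, -1, 8.3, 0.10,
    "3c", 3L, 2L, "mixed", "moderate", "+", 0.5, 0.5, 7.8, 0.10,
    "3d", 3L, 2L, "mixed", "moderate", "-", -0.5, -0.5, 7.8, 0.10,
    "3e", 3L, 2L, "high", "strong", "+", 1, 1, 8, 0.29,
    "3f", 3L, 2L, "high", "strong", "-", -1, -1, 8, 0.29,
    "3g", 3L, 2L, "high", "moderate", "+", 0.5, 0.5, 7, 0.31,
    "3h", 3L, 2L, "high", "moderate", "-", -0.5, -0.5, 7, 0.31
  ) |>
    dplyr::mutate(model_size = 5L + .data$n_interactions)
}

#' Fetch one scenario row by id
#'
#' @param scenario_id Subscenario label, e.g. `"2e"`.
#' @return A one-row tibble.
#' @export
scenario_spec <- function(scenario_id) {
  reg <- scenario_registry()
  row <- reg[reg$scenario_id == scenario_id, ]
  if (nrow(row) != 1L) {
    stop_exposelect(paste0("unknown scenario id: ", scenario_id),
                    "exposelect_config_error")
  }
  row
}

#' Draw the five true predictors
#'
#' `mixed` draws uniformly without replacement from all exposures, `high`
#' from the high-correlation block, `low` from the low-correlation block.
#'
#' @param model A `correlation_model`.
#' @param mode `"mixed"`, `"high"` or `"low"`.
#' @param seed Integer seed.
#' @return Five exposure indices, in draw order (the first is X1, etc.).
#' @export
select_true_predictors <- function(model, mode = c("mixed", "high", "low"),
                                   seed = 1L) {
  mode <- match.arg(mode)
  pool <- switch(mode,
                 mixed = seq_len(nrow(model$matrix)),
                 high = model$high_block,
                 low = model$low_block)
  if (is.null(pool)) {
    stop_exposelect(paste0("correlation model has no block for mode '",
                           mode, "'."), "exposelect_config_error")
  }
  if (length(pool) == 5L) return(pool)
  with_seed(seed, sample(pool, 5L))
}

#' Instantiate the true model of a scenario on drawn predictors
#'
#' Interaction pairs attach to the first drawn predictors: (X1, X2) for one
#' interaction and additionally (X1, X3) for two.
#'
#' @param spec A scenario row ([scenario_spec()]).
#' @param predictors Five exposure indices in draw order.
#' @param sigma Residual standard deviation override (needed when the
#'   registry row carries `NA`, e.g. scenario 2i).
#' @return A list of class `true_model` with `predictor_indices`, `beta0`,
#'   `betas`, `gammas` (tibble `i`, `j`, `gamma` in exposure indices),
#'   `sigma`.
#' @export
make_true_model <- function(spec, predictors, sigma = NULL) {
  stopifnot(length(predictors) == 5L, !anyDuplicated(predictors))
  gam <- tibble::tibble(i = integer(), j = integer(), gamma = numeric())
  if (spec$n_interactions >= 1L) {
    gam <- dplyr::bind_rows(gam, tibble::tibble(
      i = predictors[1], j = predictors[2], gamma = spec$gamma12))
  }
  if (spec$n_interactions >= 2L) {
    gam <- dplyr::bind_rows(gam, tibble::tibble(
      i = predictors[1], j = predictors[3], gamma = spec$gamma13))
  }
  sigma <- sigma %||% spec$sigma
  if (is.na(sigma)) {
    stop_exposelect("scenario sigma is not set; calibrate it first.",
                    "exposelect_config_error")
  }
  structure(list(predictor_indices = predictors, beta0 = 1,
                 betas = rep(1, 5), gammas = gam, sigma = sigma,
                 scenario_id = spec$scenario_id),
            class = "true_model")
}

#' Terms of a true model
#'
#' @param tm A `true_model`.
#' @return A term tibble: the five mains plus 0-2 interactions.
#' @export
true_terms <- function(tm) {
  t <- purrr::map_dfr(tm$predictor_indices, term_main)
  if (nrow(tm$gammas) > 0) {
    t <- dplyr::bind_rows(t, term_inter(tm$gammas$i, tm$gammas$j))
  }
  canonical_terms(t)
}

# F(E) without noise
true_signal <- function(E, tm) {
  E <- as.matrix(E)
  f <- tm$beta0 + drop(E[, tm$predictor_indices, drop = FALSE] %*% tm$betas)
  if (nrow(tm$gammas) > 0) {
    for (r in seq_len(nrow(tm$gammas))) {
      f <- f + tm$gammas$gamma[r] * E[, tm$gammas$i[r]] * E[, tm$gammas$j[r]]
    }
  }
  f
}

#' Simulate the outcome from a true model
#'
#' `Y = F(E) + eps`, `eps ~ N(0, sigma)` i.i.d.
#'
#' @param E Exposure matrix or tibble.
#' @param tm A `true_model`.
#' @param seed Integer seed for the noise.
#' @return Numeric outcome vector.
#' @export
simulate_outcome <- function(E, tm, seed = 1L) {
  f <- true_signal(E, tm)
  f + with_seed(seed, stats::rnorm(length(f), 0, tm$sigma))
}

# Var(F) in closed form for standardized Gaussian exposures:
# Var(sum beta_i X_i) = beta' R beta; products via Isserlis' theorem:
# Cov(X_a X_b, X_c X_d) = r_ac r_bd + r_ad r_bc (covers the variance case
# 1 + r_ab^2 and shared-index pairs), and Cov(X_k, X_a X_b) = 0.
var_true_signal <- function(R, predictors, betas, gammas) {
  Rp <- R[predictors, predictors, drop = FALSE]
  v <- drop(t(betas) %*% Rp %*% betas)
  ng <- nrow(gammas)
  if (ng > 0) {
    for (a in seq_len(ng)) {
      for (b in seq_len(ng)) {
        i <- gammas$i[a]; j <- gammas$j[a]
        k <- gammas$i[b]; l <- gammas$j[b]
        v <- v + gammas$gamma[a] * gammas$gamma[b] *
          (R[i, k] * R[j, l] + R[i, l] * R[j, k])
      }
    }
  }
  v
}

#' Population R-squared of a scenario on given predictors
#'
#' Computed as `Var(F) / (Var(F) + sigma^2)` with `Var(F)` in closed form
#' under multivariate-normal exposures (Isserlis' theorem for the product
#' terms; products are uncorrelated with the linear part).
#'
#' @param spec Scenario row.
#' @param model A `correlation_model`.
#' @param predictors Five exposure indices in draw order.
#' @param sigma Optional sigma override.
#' @return Population R-squared in `(0, 1)`.
#' @export
expected_r2 <- function(spec, model, predictors, sigma = NULL) {
  tm <- make_true_model(spec, predictors, sigma = sigma %||% spec$sigma)
  v <- var_true_signal(model$matrix, tm$predictor_indices, tm$betas,
                       tm$gammas)
  v / (v + tm$sigma^2)
}

#' Calibrate sigma to a target population R-squared
#'
#' Averages the closed-form `Var(F)` over seeded predictor draws for the
#' scenario's correlation mode and solves
#' `sigma = sqrt(Var(F) (1 - R2) / R2)`.
#'
#' @param spec Scenario row (its `sigma` is ignored).
#' @param model A `correlation_model`.
#' @param target_r2 Target R-squared; defaults to the registry value.
#' @param n_draws Number of predictor draws to average over.
#' @param seed Integer seed.
#' @return Calibrated sigma.
#' @export
calibrate_sigma <- function(spec, model, target_r2 = spec$target_r2,
                            n_draws = 200L, seed = 1L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  vs <- vapply(seq_len(n_draws), function(r) {
    pred <- select_true_predictors(model, spec$correlation_mode,
                                   seed = derive_seed(seed, "calib", r))
    tm <- make_true_model(spec, pred, sigma = 1)
    var_true_signal(model$matrix, tm$predictor_indices, tm$betas, tm$gammas)
  }, numeric(1))
  v <- mean(vs)
  if (v <= 0) {
    stop_exposelect("degenerate Var(F) = 0; cannot calibrate sigma.",
                    "exposelect_config_error")
  }
  sqrt(v * (1 - target_r2) / target_r2)
}

# resolve a scenario's sigma, calibrating when the registry has none
scenario_sigma <- function(spec, model, seed = 1L) {
  if (!is.na(spec$sigma)) return(spec$sigma)
  calibrate_sigma(spec, model, seed = seed)
}

#' Proportion of true terms significant when fitting only the true model
#'
#' For each replicate: draw predictors, simulate a fresh training dataset,
#' fit OLS with exactly the true terms, and record the fraction of terms
#' with p < 0.05. A diagnostic for the power calibration of a scenario.
#'
#' @param spec Scenario row.
#' @param model A `correlation_model`.
#' @param n_reps Number of replicates.
#' @param n Training sample size.
#' @param seed Integer seed.
#' @param alpha Per-term significance level.
#' @return Mean fraction of significant true terms.
#' @export
true_model_sensitivity <- function(spec, model, n_reps = 20L, n = 1200L,
                                   seed = 1L, alpha = 0.05) {
  sigma <- scenario_sigma(spec, model, seed = seed)
  mean(vapply(seq_len(n_reps), function(r) {
    pred <- select_true_predictors(model, spec$correlation_mode,
                                   seed = derive_seed(seed, "tms-pred", r))
    tm <- make_true_model(spec, pred, sigma = sigma)
    E <- simulate_exposures(model, n, seed = derive_seed(seed, "tms-E", r))
    y <- simulate_outcome(E, tm, seed = derive_seed(seed, "tms-y", r))
    fit <- ols_fit(E, y, true_terms(tm))
    p <- fit$tidy$p_value[fit$tidy$term != "(Intercept)"]
    mean(p < alpha)
  }, numeric(1)))
}

#' Simulate one training + validation study for a scenario
#'
#' Draws the true predictors, then independent training (`n_train`) and
#' validation (`n_valid`) exposure matrices from the same correlation
#' model, with outcomes from the same true model and independent noise.
#'
#' @param spec Scenario row.
#' @param model A `correlation_model`.
#' @param seed Integer replicate seed.
#' @param n_train,n_valid Sample sizes.
#' @param sigma Optional sigma override (otherwise registry value or
#'   run-time calibration).
#' @return A list of class `simulated_study`.
#' @export
simulate_study <- function(spec, model, seed = 1L, n_train = 1200L,
                           n_valid = 10000L, sigma = NULL) {
  sigma <- sigma %||% scenario_sigma(spec, model, seed = seed)
  pred <- select_true_predictors(model, spec$correlation_mode,
                                 seed = derive_seed(seed, "pred"))
  tm <- make_true_model(spec, pred, sigma = sigma)
  E_tr <- simulate_exposures(model, n_train, seed = derive_seed(seed, "Etr"))
  y_tr <- simulate_outcome(E_tr, tm, seed = derive_seed(seed, "ytr"))
  E_va <- simulate_exposures(model, n_valid, seed = derive_seed(seed, "Eva"))
  y_va <- simulate_outcome(E_va, tm, seed = derive_seed(seed, "yva"))
  structure(list(train = E_tr, y_train = y_tr, valid = E_va,
                 y_valid = y_va, true_model = tm, spec = spec, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> scenario ", x$spec$scenario_id, ", n_train ",
      nrow(x$train), ", n_valid ", nrow(x$valid), "\n", sep = "")
  invisible(x)
}
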