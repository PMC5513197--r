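#' Compare a selection with the true model
#'
#' Builds the sets underlying the performance measures: `A` (true
#' predictors), `B` (variables in the fitted model), `A2`/`B2` (variables
#' involved in true / fitted interaction terms), and the exact term sets.
#'
#' @param selected A `selected_model`.
#' @param tm A `true_model`.
#' @return A list of class `selection_comparison`.
#' @export
selection_comparison <- function(selected, tm) {
  tt <- true_terms(tm)
  ft <- selected$terms
  A <- sort(tm$predictor_indices)
  B <- model_variables(selected)
  A2 <- sort(unique(c(tm$gammas$i, tm$gammas$j)))
  fi <- ft[ft$kind == "inter", , drop = FALSE]
  B2 <- sort(unique(c(fi$i, fi$j)))
  structure(list(A = A, B = B, A2 = A2, B2 = B2,
                 true_terms = tt, fitted_terms = ft,
                 true_inter = tt[tt$kind == "inter", , drop = FALSE],
                 fitted_inter = fi),
            class = "selection_comparison")
}

# mean over rows of A of the maximum |corr| with columns B
avg_max_abs_corr <- function(R, from, to) {
  if (length(from) == 0L || length(to) == 0L) return(NA_real_)
  sub <- abs(R[from, to, drop = FALSE])
  mean(apply(sub, 1, max))
}

match_count <- function(x, y) {
  if (nrow(x) == 0L) return(0L)
  sum(term_labels(x) %in% term_labels(y))
}

#' The thirteen performance measures of one selection
#'
#' Term-level measures (relative model size, sensitivity, false discovery
#' proportion and their interaction-only versions) compare exact term sets;
#' variable-level measures compare the sets of involved exposures; the
#' alternative measures credit or discount proxies through the maximum
#' absolute correlation, taken from the data-generating correlation model.
#' The relative out-of-sample R-squared divides the fitted model's
#' validation R-squared by that of an OLS fit of the true terms. Measures a
#' method cannot provide (per its capability flags) are reported `NA`, as
#' are alternative measures of an empty selection.
#'
#' @param selected A `selected_model`.
#' @param study A `simulated_study`.
#' @param model The `correlation_model` that generated the exposures.
#' @return A one-row tibble with the 13 measures plus bookkeeping columns.
#' @export
evaluate_selection <- function(selected, study, model) {
  tm <- study$true_model
  cmp <- selection_comparison(selected, tm)
  R <- abs(model$matrix)
  n_true_terms <- nrow(cmp$true_terms)
  n_fit_terms <- nrow(cmp$fitted_terms)
  n_true_inter <- nrow(cmp$true_inter)
  n_fit_inter <- nrow(cmp$fitted_inter)
  empty <- n_fit_terms == 0L

  term_level <- isTRUE(selected$term_level)
  inter_level <- term_level && isTRUE(selected$searches_interactions)

  rms <- if (term_level) n_fit_terms / n_true_terms else NA_real_
  rnv <- length(cmp$B) / length(cmp$A)

  sens <- if (term_level) {
    match_count(cmp$true_terms, cmp$fitted_terms) / n_true_terms
  } else NA_real_
  sens_var <- length(intersect(cmp$A, cmp$B)) / length(cmp$A)
  sens2 <- if (!inter_level || n_true_inter == 0L) NA_real_ else {
    match_count(cmp$true_inter, cmp$fitted_inter) / n_true_inter
  }

  alt_sens <- if (empty) NA_real_ else avg_max_abs_corr(R, cmp$A, cmp$B)
  alt_sens2 <- if (!inter_level || n_true_inter == 0L) NA_real_ else {
    avg_max_abs_corr(R, cmp$A2, cmp$B2)
  }

  fdp <- if (!term_level) NA_real_ else if (empty) 0 else {
    (n_fit_terms - match_count(cmp$fitted_terms, cmp$true_terms)) /
      n_fit_terms
  }
  fdp_var <- if (length(cmp$B) == 0L) 0 else {
    length(setdiff(cmp$B, cmp$A)) / length(cmp$B)
  }
  fdp2 <- if (!inter_level) NA_real_ else if (n_fit_inter == 0L) 0 else {
    (n_fit_inter - match_count(cmp$fitted_inter, cmp$true_inter)) /
      n_fit_inter
  }
  alt_fdp <- if (length(cmp$B) == 0L) NA_real_ else {
    1 - avg_max_abs_corr(R, cmp$B, cmp$A)
  }
  alt_fdp2 <- if (!inter_level || n_fit_inter == 0L ||
                  n_true_inter == 0L) NA_real_ else {
    1 - avg_max_abs_corr(R, cmp$B2, cmp$A2)
  }

  r2_rel <- if (isTRUE(selected$predicts) &&
                !is.null(selected$predict_fn)) {
    r2_relative(selected, study)
  } else NA_real_

  tibble::tibble(method = selected$method,
                 rms = rms, rnv = rnv, r2_rel = r2_rel,
                 sens = sens, alt_sens = alt_sens, sens_var = sens_var,
                 sens2 = sens2, alt_sens2 = alt_sens2,
                 fdp = fdp, alt_fdp = alt_fdp, fdp_var = fdp_var,
                 fdp2 = fdp2, alt_fdp2 = alt_fdp2,
                 n_terms = n_fit_terms, n_variables = length(cmp$B),
                 empty_model = empty)
}

#' Relative out-of-sample R-squared
#'
#' Numerator: validation R-squared of the method's native predictor.
#' Denominator: validation R-squared of the OLS fit (on the training data)
#' of exactly the true terms. Either may be negative; the ratio can exceed
#' one.
#'
#' @param selected A `selected_model` with a `predict_fn`.
#' @param study A `simulated_study`.
#' @return The ratio of out-of-sample R-squared values.
#' @export
r2_relative <- function(selected, study) {
  yv <- study$y_valid
  tss <- sum((yv - mean(yv))^2)
  if (tss < 1e-12) {
    stop_exposelect("validation outcome has zero variance.",
                    "exposelect_fit_error")
  }
  truth_fit <- ols_fit(study$train, study$y_train,
                       true_terms(study$true_model))
  co <- truth_fit$tidy$estimate
  Xv <- cbind(1, design_columns(study$valid, true_terms(study$true_model)))
  r2_den <- 1 - sum((yv - drop(Xv %*% co))^2) / tss
  pred <- selected$predict_fn(study$valid)
  r2_num <- 1 - sum((yv - pred)^2) / tss
  r2_num / r2_den
}
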