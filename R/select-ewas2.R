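# split a data frame into exposure matrix + outcome vector
split_exposures <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    stop_exposelect(paste0("no outcome column '", outcome, "' in data."),
                    "exposelect_config_error")
  }
  y <- data[[outcome]]
  E <- as.matrix(data[setdiff(names(data), outcome)])
  storage.mode(E) <- "double"
  list(E = E, y = as.numeric(y))
}

# marginal (single-exposure) two-sided p-values, via the correlation t-test,
# which is exact for the simple-regression slope
marginal_pvalues <- function(E, y) {
  n <- nrow(E)
  r <- suppressWarnings(as.vector(stats::cor(E, y)))
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  p[is.na(p)] <- 1
  p
}

#' Two-step exposome-wide association study (EWAS2)
#'
#' Step 1 tests each exposure marginally in a single-exposure linear
#' regression and keeps the exposures surviving a Benjamini-Yekutieli
#' correction at level `alpha`. Step 2 fits, for every unordered pair of
#' survivors, a linear model with the two mains plus their product, collects
#' the interaction p-values, applies Benjamini-Yekutieli again, and keeps
#' the surviving interaction terms. The result is a set of marginal
#' associations, not a single fitted model, so it carries no predictor.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param alpha Significance level for both correction steps.
#' @return A `selected_model` with `has_single_model = FALSE`.
#' @export
ewas2 <- function(data, outcome = "y", alpha = 0.05) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  if (nrow(E) <= 4) {
    stop_exposelect("need more than 4 observations.", "exposelect_fit_error")
  }
  p1 <- marginal_pvalues(E, y)
  survivors <- which(benjamini_yekutieli(p1, alpha))
  terms <- purrr::map_dfr(survivors, term_main)
  n_pairs <- 0L
  if (length(survivors) >= 2L) {
    pairs <- utils::combn(survivors, 2L)
    n_pairs <- ncol(pairs)
    ip <- vapply(seq_len(n_pairs), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      fit <- ols_fit(E, y, dplyr::bind_rows(term_main(i), term_main(j),
                                            term_inter(i, j)))
      pv <- fit$tidy$p_value[fit$tidy$term == paste0("inter:", i, ":", j)]
      if (length(pv) == 0 || is.na(pv)) 1 else pv
    }, numeric(1))
    sig <- benjamini_yekutieli(ip, alpha)
    if (any(sig)) {
      terms <- dplyr::bind_rows(terms,
                                term_inter(pairs[1, sig], pairs[2, sig]))
    }
  }
  selected_model("EWAS2", terms, has_single_model = FALSE, predicts = FALSE,
                 searches_interactions = TRUE, term_level = TRUE,
                 info = list(n_step1_survivors = length(survivors),
                             n_pairs_tested = n_pairs,
                             step1_pvalues = p1))
}
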