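#' Model terms: main effects, quadratics and pairwise interactions
#'
#' Terms are represented as a tibble with columns `kind` (`"main"`,
#' `"quad"` or `"inter"`), `i` and `j` (exposure indices; `j` is `NA`
#' except for interactions, which are stored unordered with `i < j`).
#' A model with terms \eqn{X_1, X_2, X_1^2, X_1 X_2} contains four terms
#' and two variables.
#'
#' @param i,j Exposure indices.
#' @return A one-row term tibble.
#' @export
term_main <- function(i) tibble::tibble(kind = "main", i = as.integer(i),
                                        j = NA_integer_)

#' @rdname term_main
#' @export
term_quad <- function(i) tibble::tibble(kind = "quad", i = as.integer(i),
                                        j = NA_integer_)

#' @rdname term_main
#' @export
term_inter <- function(i, j) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) {
    stop_exposelect("an interaction needs two distinct exposures.",
                    "exposelect_term_error")
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  tibble::tibble(kind = "inter", i = lo, j = hi)
}

# canonical ordering: mains by index, then quads, then interactions
# lexicographically; duplicates dropped
canonical_terms <- function(terms) {
  if (is.null(terms) || nrow(terms) == 0L ||
      !all(c("kind", "i", "j") %in% names(terms))) {
    return(tibble::tibble(kind = character(), i = integer(), j = integer()))
  }
  terms <- dplyr::distinct(terms, .data$kind, .data$i, .data$j)
  kind_rank <- match(terms$kind, c("main", "quad", "inter"))
  terms[order(kind_rank, terms$i, terms$j), , drop = FALSE]
}

term_labels <- function(terms) {
  if (nrow(terms) == 0L || !"kind" %in% names(terms)) return(character(0))
  ifelse(terms$kind == "inter",
         paste0("inter:", terms$i, ":", terms$j),
         paste0(terms$kind, ":", terms$i))
}

#' Construct a selection result
#'
#' The common container returned by every selector: a set of terms with
#' optional coefficients, plus capability flags controlling which
#' performance measures apply. `predict_fn`, when present, maps an exposure
#' matrix to predictions using the method's native predictor.
#'
#' @param method Selector name.
#' @param terms Term tibble (see [term_main()]).
#' @param coefficients Optional numeric vector aligned with `terms` rows.
#' @param intercept Optional intercept.
#' @param has_single_model Does the method return one fitted model?
#' @param predicts Does the method yield a predictor function?
#' @param searches_interactions Does the method's search space include
#'   pairwise interaction terms?
#' @param term_level Are term-level measures meaningful (FALSE for ensemble
#'   methods whose "terms" are only variable bookkeeping)?
#' @param predict_fn Optional function(matrix) -> numeric.
#' @param info Free-form list of per-method diagnostics.
#' @return An object of class `selected_model`.
#' @export
selected_model <- function(method, terms, coefficients = NULL,
                           intercept = NULL, has_single_model = TRUE,
                           predicts = TRUE, searches_interactions = TRUE,
                           term_level = TRUE, predict_fn = NULL,
                           info = list()) {
  raw <- terms %||% tibble::tibble(kind = character(), i = integer(),
                                   j = integer())
  terms <- canonical_terms(raw)
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) &&
        length(coefficients) == nrow(raw)) {
      # positional: permute alongside the canonical reordering
      names(coefficients) <- term_labels(raw)
    }
    if (is.null(names(coefficients))) {
      stop_exposelect("coefficients do not align with terms.",
                      "exposelect_term_error")
    }
    coefficients <- coefficients[term_labels(terms)]
    names(coefficients) <- term_labels(terms)
  }
  structure(list(method = method, terms = terms,
                 coefficients = coefficients, intercept = intercept,
                 has_single_model = has_single_model, predicts = predicts,
                 searches_interactions = searches_interactions,
                 term_level = term_level, predict_fn = predict_fn,
                 info = info),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  cat("<selected_model> method ", x$method, ": ", count_terms(x),
      " terms, ", count_variables(x), " variables\n", sep = "")
  invisible(x)
}

#' Count terms / variables of a selection
#'
#' The model size is the number of terms excluding the intercept; the
#' variables are the distinct exposures appearing in any term.
#'
#' @param model A `selected_model` (or bare term tibble).
#' @return An integer.
#' @export
count_terms <- function(model) {
  terms <- if (inherits(model, "selected_model")) model$terms else model
  nrow(terms)
}

#' @rdname count_terms
#' @export
count_variables <- function(model) {
  length(model_variables(model))
}

#' @rdname count_terms
#' @export
model_variables <- function(model) {
  terms <- if (inherits(model, "selected_model")) model$terms else model
  sort(unique(c(terms$i, terms$j[!is.na(terms$j)])))
}

#' @export
tidy.selected_model <- function(x, ...) {
  out <- x$terms
  out$term <- term_labels(out)
  if (!is.null(x$coefficients)) out$estimate <- unname(x$coefficients)
  dplyr::relocate(out, "term")
}

#' @export
glance.selected_model <- function(x, ...) {
  tibble::tibble(method = x$method, n_terms = count_terms(x),
                 n_variables = count_variables(x),
                 n_interactions = sum(x$terms$kind == "inter"),
                 has_single_model = x$has_single_model,
                 predicts = x$predicts)
}

#' Build the design matrix for a set of terms
#'
#' Main terms map to the exposure column, quadratics to its square,
#' interactions to the elementwise product. Columns follow the canonical
#' term order.
#'
#' @param E Exposure matrix or data frame (rows = subjects).
#' @param terms Term tibble.
#' @return A numeric matrix with one column per term.
#' @export
design_columns <- function(E, terms) {
  E <- as.matrix(E)
  terms <- canonical_terms(terms)
  idx <- c(terms$i, terms$j[!is.na(terms$j)])
  if (nrow(terms) > 0 && (max(idx) > ncol(E) || min(idx) < 1)) {
    stop_exposelect("term index outside the exposure matrix.",
                    "exposelect_term_error")
  }
  X <- matrix(0, nrow(E), nrow(terms))
  for (k in seq_len(nrow(terms))) {
    X[, k] <- switch(terms$kind[k],
                     main = E[, terms$i[k]],
                     quad = E[, terms$i[k]]^2,
                     inter = E[, terms$i[k]] * E[, terms$j[k]])
  }
  colnames(X) <- term_labels(terms)
  X
}

#' Ordinary least squares with per-term t-tests
#'
#' Fits `y ~ intercept + terms` and reports two-sided t-test p-values with
#' `n - k - 1` degrees of freedom. Rank-deficient designs are fitted through
#' the pseudo-inverse and flagged; their p-values are reported missing.
#'
#' @param E Exposure matrix or data frame.
#' @param y Outcome vector.
#' @param terms Term tibble (may be empty: intercept-only fit).
#' @return A list with elements `tidy` (term, estimate, se, p_value,
#'   including the intercept), `sigma2`, `df`, `rank_deficient`, `rss`,
#'   `fitted`.
#' @export
ols_fit <- function(E, y, terms) {
  terms <- canonical_terms(terms)
  X <- cbind(`(Intercept)` = 1, design_columns(E, terms))
  n <- length(y); k <- ncol(X)
  if (n <= k) {
    stop_exposelect("need more observations than coefficients.",
                    "exposelect_fit_error")
  }
  qx <- qr(X)
  rank_def <- qx$rank < k
  if (!rank_def) {
    beta <- qr.coef(qx, y)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    rss <- sum(res^2)
    df <- n - k
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qx))
    se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
    tval <- beta / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  } else {
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
    names(beta) <- colnames(X)
    fitted <- drop(X %*% beta)
    res <- y - fitted
    rss <- sum(res^2)
    df <- n - qx$rank
    sigma2 <- rss / max(df, 1)
    se <- rep(NA_real_, k)
    pval <- rep(NA_real_, k)
  }
  list(tidy = tibble::tibble(term = colnames(X), estimate = unname(beta),
                             se = unname(se), p_value = unname(pval)),
       sigma2 = sigma2, df = df, rank_deficient = rank_def, rss = rss,
       fitted = fitted)
}

# adjusted R^2 with k fitted terms (intercept excluded from k)
adjusted_r2 <- function(y, fitted, k) {
  n <- length(y)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Benjamini-Yekutieli significance mask
#'
#' Step-up rule at level `alpha` with the dependence-robust correction
#' factor \eqn{c(m) = \sum_{l=1}^m 1/l}: declare significant every p-value
#' at most the largest \eqn{p_{(i)}} satisfying
#' \eqn{p_{(i)} \le i\,\alpha/(m\,c(m))}.
#'
#' @param pvals Vector of p-values in `[0, 1]`.
#' @param alpha Target false discovery rate.
#' @return Logical mask aligned with `pvals`.
#' @export
benjamini_yekutieli <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0L) return(logical(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_exposelect("p-values must be in [0, 1].", "exposelect_fit_error")
  }
  stats::p.adjust(pvals, method = "BY") <= alpha
}

#' Write / read a selection as line-oriented text
#'
#' One line per term: `main i`, `quad i` or `inter i j`, with an optional
#' trailing coefficient column.
#'
#' @param model A `selected_model`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `selected_model` (reader).
#' @export
write_selected_model <- function(model, path) {
  t <- model$terms
  lines <- ifelse(t$kind == "inter",
                  paste(t$kind, t$i, t$j),
                  paste(t$kind, t$i))
  if (!is.null(model$coefficients)) {
    lines <- paste(lines, format(model$coefficients, digits = 12,
                                 trim = TRUE))
  }
  writeLines(c(paste("# method", model$method), lines), path)
  invisible(path)
}

#' @rdname write_selected_model
#' @export
read_selected_model <- function(path) {
  lines <- readLines(path)
  method <- sub("^# method ", "", lines[1])
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  terms <- purrr::map_dfr(parts, function(x) {
    switch(x[1],
           main = term_main(as.integer(x[2])),
           quad = term_quad(as.integer(x[2])),
           inter = term_inter(as.integer(x[2]), as.integer(x[3])))
  })
  coefs <- purrr::map_dbl(parts, function(x) {
    v <- suppressWarnings(as.numeric(x[length(x)]))
    if (x[1] == "inter" && length(x) == 3L) NA_real_
    else if (x[1] != "inter" && length(x) == 2L) NA_real_
    else v
  })
  selected_model(method, terms,
                 coefficients = if (!all(is.na(coefs))) coefs)
}
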