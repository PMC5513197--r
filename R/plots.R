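#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Histogram of the absolute off-diagonal correlations of a model
#'
#' @param object A `correlation_model`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.correlation_model <- function(object, bins = 60, ...) {
  a <- off_diag_abs(object$matrix)
  ggplot2::ggplot(tibble::tibble(abs_r = a),
                  ggplot2::aes(x = .data$abs_r)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::geom_vline(xintercept = c(0.1, 0.2, 0.6), linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "|pairwise correlation|", y = "pairs",
                  title = "Exposome correlation structure") +
    ggplot2::theme_minimal()
}

#' Scenario-by-method chart of aggregated benchmark measures
#'
#' @param object A long results tibble from [run_benchmark()].
#' @param metrics Which measures to facet.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_results <- function(object,
                                       metrics = c("sens_var", "alt_sens",
                                                   "fdp_var", "alt_fdp"),
                                       ...) {
  agg <- aggregate_results(object)
  agg <- agg[agg$metric %in% metrics & !is.na(agg$mean_value), ]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$scenario_id,
                                    y = .data$mean_value,
                                    colour = .data$method,
                                    group = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = "mean over replicates") +
    ggplot2::theme_minimal()
}

#' Cross-validation curve plot for a penalized path
#'
#' @param curve The `curve` tibble returned by [cv_curve()] (columns
#'   lambda, mean_error, se_error).
#' @return A ggplot.
#' @export
plot_cv_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = log(.data$lambda),
                                      y = .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error -
                                        .data$se_error,
                                      ymax = .data$mean_error +
                                        .data$se_error),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log(lambda)", y = "CV mean squared error") +
    ggplot2::theme_minimal()
}
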