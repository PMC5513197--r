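#' Configuration of a full benchmark run
#'
#' @param scenario_ids Subscenario labels to run (subset of
#'   [scenario_registry()]).
#' @param methods Selector names among `"EWAS2"`, `"DSA1"`, `"DSA2"`,
#'   `"Sun3step"`, `"LASSO"`, `"GLINTERNET"`, `"BRT"`.
#' @param n_replicates Replicates per subscenario.
#' @param n_train,n_valid Training and validation sample sizes.
#' @param master_seed Single seed from which every replicate, fold and
#'   noise stream is derived.
#' @param generator A [generator_config()] for the correlation model (its
#'   seed is re-derived from `master_seed` unless supplied explicitly).
#' @param out_dir Optional directory; per-replicate results are streamed to
#'   CSV there and finished replicates are skipped on re-run.
#' @param method_configs Optional named list overriding per-method
#'   configurations (`dsa1`, `dsa2`, `sun3step`, `penalized`, `brt`).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(scenario_ids = scenario_registry()$scenario_id,
                             methods = c("EWAS2", "DSA1", "DSA2",
                                         "Sun3step", "LASSO", "GLINTERNET",
                                         "BRT"),
                             n_replicates = 100L, n_train = 1200L,
                             n_valid = 10000L, master_seed = 1L,
                             generator = NULL, out_dir = NULL,
                             method_configs = list()) {
  stopifnot(n_replicates >= 1, length(methods) >= 1)
  known <- c("EWAS2", "DSA1", "DSA2", "Sun3step", "LASSO", "GLINTERNET",
             "BRT")
  if (!all(methods %in% known)) {
    stop_exposelect(paste0("unknown method(s): ",
                           paste(setdiff(methods, known), collapse = ", ")),
                    "exposelect_config_error")
  }
  structure(list(scenario_ids = scenario_ids, methods = methods,
                 n_replicates = as.integer(n_replicates),
                 n_train = as.integer(n_train),
                 n_valid = as.integer(n_valid),
                 master_seed = as.integer(master_seed),
                 generator = generator, out_dir = out_dir,
                 method_configs = method_configs),
            class = "benchmark_config")
}

# run one selector on one study; seeds derived from the replicate seed
run_selector <- function(method, study, model, seed, method_configs) {
  data <- study$train
  data$.y <- study$y_train
  mc <- method_configs
  switch(method,
    EWAS2 = ewas2(data, outcome = ".y"),
    DSA1 = dsa(data, outcome = ".y",
               config = mc$dsa1 %||% dsa_config(maxorder = 1L,
                                                seed = seed)),
    DSA2 = dsa(data, outcome = ".y",
               config = mc$dsa2 %||% dsa_config(maxorder = 2L,
                                                seed = seed)),
    Sun3step = sun3step(data, outcome = ".y",
                        families = model$family_labels,
                        config = mc$sun3step %||% sun3step_config(seed = seed)),
    LASSO = lasso_select(data, outcome = ".y",
                         config = mc$penalized %||% penalized_config(seed = seed)),
    GLINTERNET = glinternet_select(data, outcome = ".y",
                                   config = mc$penalized %||%
                                     penalized_config(seed = seed)),
    BRT = brt_variable_selection(data, outcome = ".y",
                                 config = mc$brt %||% brt_config(seed = seed)),
    stop_exposelect(paste0("unknown method: ", method),
                    "exposelect_config_error"))
}

metric_names <- function() {
  c("rms", "rnv", "r2_rel", "sens", "alt_sens", "sens_var", "sens2",
    "alt_sens2", "fdp", "alt_fdp", "fdp_var", "fdp2", "alt_fdp2")
}

#' Run the benchmark loop
#'
#' Builds the correlation model once, then for every subscenario and
#' replicate simulates one training + validation study, runs every
#' requested method on the identical training data, and evaluates the 13
#' measures. All randomness is derived from `master_seed`; a failing
#' method-run is recorded as failed and the loop continues. Results are in
#' long format: one row per (scenario, method, replicate, metric).
#'
#' @param config A [benchmark_config()].
#' @param model Optional pre-built `correlation_model` (otherwise built
#'   from `config$generator`).
#' @return A tibble of class `benchmark_results`.
#' @export
run_benchmark <- function(config = benchmark_config(), model = NULL) {
  if (is.null(model)) {
    gen <- config$generator %||%
      generator_config(seed = derive_seed(config$master_seed, "sigma"))
    model <- build_correlation_model(gen)
  }
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  rows <- list()
  for (sid in config$scenario_ids) {
    spec <- scenario_spec(sid)
    sigma <- scenario_sigma(spec, model,
                            seed = derive_seed(config$master_seed, "sigma",
                                               sid))
    for (rep_i in seq_len(config$n_replicates)) {
      cache <- if (!is.null(config$out_dir)) {
        file.path(config$out_dir, sprintf("rep_%s_%03d.csv", sid, rep_i))
      }
      if (!is.null(cache) && file.exists(cache)) {
        rows[[length(rows) + 1L]] <-
          tibble::as_tibble(utils::read.csv(cache))
        next
      }
      rep_seed <- derive_seed(config$master_seed, "rep", sid, rep_i)
      study <- simulate_study(spec, model, seed = rep_seed,
                              n_train = config$n_train,
                              n_valid = config$n_valid, sigma = sigma)
      rep_rows <- purrr::map_dfr(config$methods, function(m) {
        res <- tryCatch({
          sel <- run_selector(m, study, model,
                              derive_seed(rep_seed, "method", m),
                              config$method_configs)
          ev <- evaluate_selection(sel, study, model)
          tidyr::pivot_longer(ev[, c("method", metric_names())],
                              -"method", names_to = "metric",
                              values_to = "value") |>
            dplyr::mutate(failed = FALSE)
        }, error = function(e) {
          tibble::tibble(method = m, metric = metric_names(),
                         value = NA_real_, failed = TRUE)
        })
        res
      })
      rep_rows <- dplyr::mutate(rep_rows, scenario_id = sid,
                                replicate = rep_i,
                                missing = is.na(.data$value)) |>
        dplyr::relocate("scenario_id", "method", "replicate")
      if (!is.null(cache)) utils::write.csv(rep_rows, cache,
                                            row.names = FALSE)
      rows[[length(rows) + 1L]] <- rep_rows
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("benchmark_results", class(out))
  out
}

#' Aggregate benchmark results
#'
#' Arithmetic mean over the non-missing replicates of each
#' (scenario, method, metric), with the replicate counts retained.
#'
#' @param results A long results tibble from [run_benchmark()].
#' @return A tibble with one row per (scenario_id, method, metric).
#' @export
aggregate_results <- function(results) {
  dplyr::group_by(results, .data$scenario_id, .data$method, .data$metric) |>
    dplyr::summarise(mean_value = if (all(is.na(.data$value))) NA_real_
                                  else mean(.data$value, na.rm = TRUE),
                     n_used = sum(!is.na(.data$value)),
                     n_failed = sum(.data$failed),
                     .groups = "drop")
}

#' Ratios of scenario-level mean measures between paired methods
#'
#' For each requested pair "numerator:denominator" (e.g. the
#' interaction-capable version over the mains-only version), computes the
#' ratio of mean metrics per scenario — the cost, when no interaction
#' truly exists, of also searching for interactions.
#'
#' @param results A long results tibble from [run_benchmark()].
#' @param pairs Character vector like `c("DSA2:DSA1", "GLINTERNET:LASSO")`.
#' @param metrics Metric names to report.
#' @return A tibble with columns scenario_id, pair, metric, ratio.
#' @export
ratio_report <- function(results, pairs = c("DSA2:DSA1",
                                            "GLINTERNET:LASSO"),
                         metrics = c("sens", "fdp")) {
  agg <- aggregate_results(results)
  out <- list()
  for (pr in pairs) {
    mm <- strsplit(pr, ":", fixed = TRUE)[[1]]
    if (length(mm) != 2L) {
      stop_exposelect("pairs must look like 'NUM:DEN'.",
                      "exposelect_config_error")
    }
    num <- agg[agg$method == mm[1] & agg$metric %in% metrics, ]
    den <- agg[agg$method == mm[2] & agg$metric %in% metrics, ]
    j <- dplyr::inner_join(num, den,
                           by = c("scenario_id", "metric"),
                           suffix = c("_num", "_den"))
    out[[pr]] <- dplyr::transmute(j, .data$scenario_id, pair = pr,
                                  .data$metric,
                                  ratio = ifelse(abs(.data$mean_value_den) <
                                                   1e-12, NA_real_,
                                                 .data$mean_value_num /
                                                   .data$mean_value_den))
  }
  dplyr::bind_rows(out)
}

#' Write / read benchmark results as CSV
#'
#' @param results A results tibble.
#' @param path CSV path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("benchmark_results", class(out))
  out
}
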