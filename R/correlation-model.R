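#' Configuration for the synthetic exposome correlation generator
#'
#' The generator emulates the correlation structure of a real exposome:
#' `p` standardized exposures organised in families, most pairs nearly
#' uncorrelated, a minority of moderately correlated pairs (shared sources,
#' shared biology), and tight clusters of highly inter-correlated exposures
#' (e.g. congener series). Two special blocks are always present: a
#' 13-exposure block whose pairwise absolute correlations all exceed 0.62
#' (used to draw "high-correlation" true predictors) and a 13-exposure set
#' whose pairwise absolute correlations are all at most 0.1.
#'
#' @param p Number of exposures (default 237).
#' @param family_sizes Integer vector of family sizes summing to `p`
#'   (default: 15 families with sizes from 1 to 51).
#' @param target_stats Named list of calibration targets for the off-diagonal
#'   absolute correlations: `frac_below_0.2`, `frac_below_0.1`, `median_abs`,
#'   `partner_frac` (fraction of exposures with at least one partner above
#'   `partner_threshold`), `partner_threshold`, and `high_block_mean` (mean
#'   pairwise correlation inside the high block).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param cluster_size_range Size range for the high-correlation clusters
#'   that give most exposures a strongly correlated partner.
#' @param n_mid_factors Number of cross-family "source profile" factors;
#'   each correlated entity belongs to exactly one, which creates the
#'   moderate-correlation band.
#' @param scales Named numeric starting values for the loading scales
#'   (`bg`, `mid`, `fam`); the first two are tuned by the calibration loop.
#' @param independent If `TRUE`, return the identity correlation matrix
#'   (diagnostic mode; no blocks, no calibration).
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(p = 237,
                             family_sizes = c(51, 38, 30, 24, 20, 16, 13,
                                              11, 9, 8, 7, 4, 3, 2, 1),
                             target_stats = list(frac_below_0.2 = 0.81,
                                                 frac_below_0.1 = 0.64,
                                                 median_abs = 0.06,
                                                 partner_frac = 0.78,
                                                 partner_threshold = 0.6,
                                                 high_block_mean = 0.78),
                             seed = 1L,
                             cluster_size_range = c(7L, 11L),
                             n_mid_factors = 4L,
                             scales = c(bg = 1.0, mid = 1.0),
                             independent = FALSE) {
  if (sum(family_sizes) != p) {
    stop_exposelect("`family_sizes` must sum to `p`.", "exposelect_config_error")
  }
  if (any(family_sizes < 1)) {
    stop_exposelect("family sizes must be positive.", "exposelect_config_error")
  }
  ts <- target_stats
  fr <- c(ts$frac_below_0.2, ts$frac_below_0.1, ts$partner_frac)
  if (any(fr < 0 | fr > 1)) {
    stop_exposelect("fraction targets must lie in [0, 1].",
                    "exposelect_config_error")
  }
  structure(list(p = as.integer(p),
                 n_families = length(family_sizes),
                 family_sizes = as.integer(family_sizes),
                 target_stats = ts, seed = as.integer(seed),
                 cluster_size_range = as.integer(cluster_size_range),
                 n_mid_factors = as.integer(n_mid_factors),
                 scales = scales, independent = isTRUE(independent)),
            class = "generator_config")
}

#' Wrap a user-supplied correlation matrix as a correlation model
#'
#' For simulation from an existing exposure correlation structure instead
#' of the synthetic generator. The matrix must be symmetric with unit
#' diagonal and positive semi-definite (repair with
#' [nearest_positive_definite()] first if needed). Blocks are optional;
#' without them the `high`/`low` predictor-draw modes are unavailable.
#'
#' @param matrix Correlation matrix.
#' @param family_labels Integer family label per exposure (defaults to a
#'   single family).
#' @param high_block,low_block Optional index vectors of the
#'   high/low-correlation blocks (13 exposures each, all pairwise
#'   |r| >= 0.62 resp. <= 0.1).
#' @return A `correlation_model`.
#' @export
correlation_model <- function(matrix, family_labels = NULL,
                              high_block = NULL, low_block = NULL) {
  family_labels <- family_labels %||% rep(1L, nrow(matrix))
  validate_correlation_model(
    new_correlation_model(matrix, family_labels, high_block, low_block))
}

new_correlation_model <- function(matrix, family_labels, high_block,
                                  low_block, clusters = NULL) {
  ids <- sprintf("exp%03d", seq_len(nrow(matrix)))
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix,
                 family_labels = as.integer(family_labels),
                 high_block = high_block, low_block = low_block,
                 clusters = clusters, exposure_ids = ids),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat("<correlation_model> ", nrow(x$matrix), " exposures, ",
      length(unique(x$family_labels)), " families\n", sep = "")
  if (!is.null(x$high_block)) {
    cat("  high block: ", length(x$high_block), " exposures; low block: ",
        length(x$low_block), " exposures\n", sep = "")
  }
  invisible(x)
}

validate_correlation_model <- function(model, tol = 1e-8) {
  M <- model$matrix
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > tol) {
    stop_exposelect("correlation matrix is not symmetric.",
                    "exposelect_model_error")
  }
  if (max(abs(diag(M) - 1)) > tol) {
    stop_exposelect("correlation matrix diagonal is not 1.",
                    "exposelect_model_error")
  }
  if (max(abs(M)) > 1 + tol) {
    stop_exposelect("correlation entries must lie in [-1, 1].",
                    "exposelect_model_error")
  }
  ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol) {
    stop_exposelect(sprintf("matrix is not PSD (min eigenvalue %.3g); run nearest_positive_definite().", ev),
                    "exposelect_model_error")
  }
  if (!is.null(model$high_block)) {
    hb <- model$high_block
    if (length(hb) != 13L || any(hb < 1 | hb > nrow(M))) {
      stop_exposelect("high block must contain 13 valid indices.",
                      "exposelect_model_error")
    }
    sub <- abs(M[hb, hb])
    if (min(sub[upper.tri(sub)]) < 0.62) {
      stop_exposelect("high-block pairwise |r| must all be >= 0.62.",
                      "exposelect_model_error")
    }
  }
  if (!is.null(model$low_block)) {
    lb <- model$low_block
    if (length(lb) != 13L || any(lb < 1 | lb > nrow(M))) {
      stop_exposelect("low block must contain 13 valid indices.",
                      "exposelect_model_error")
    }
    sub <- abs(M[lb, lb])
    if (max(sub[upper.tri(sub)]) > 0.1) {
      stop_exposelect("low-block pairwise |r| must all be <= 0.1.",
                      "exposelect_model_error")
    }
  }
  invisible(model)
}

# Partition the clustered exposures into within-family high-correlation
# clusters covering `n_covered` exposures in total (the high block counts
# towards coverage and lives in the largest family).
plan_structure <- function(config) {
  p <- config$p
  fam <- rep(seq_along(config$family_sizes), config$family_sizes)
  high_block <- which(fam == 1L)[1:13]
  n_covered <- round(config$target_stats$partner_frac * p)
  need <- n_covered - 13L
  clusters <- list()
  used <- rep(FALSE, p)
  used[high_block] <- TRUE
  rng <- config$cluster_size_range
  for (f in seq_along(config$family_sizes)) {
    repeat {
      avail <- which(fam == f & !used)
      if (need < 2L || length(avail) < 2L) break
      s <- sample(seq(rng[1], rng[2]), 1L)
      s <- min(s, length(avail), need)
      if (s < 2L) break
      members <- avail[seq_len(s)]
      clusters[[length(clusters) + 1L]] <- members
      used[members] <- TRUE
      need <- need - s
    }
  }
  if (need == 1L && length(clusters) > 0L) {
    # attach a leftover singleton to the last cluster's family if possible
    f <- fam[clusters[[length(clusters)]][1]]
    avail <- which(fam == f & !used)
    if (length(avail) > 0) {
      clusters[[length(clusters)]] <- c(clusters[[length(clusters)]], avail[1])
      used[avail[1]] <- TRUE
      need <- 0L
    }
  }
  uncov <- which(!used)
  if (length(uncov) < 13L) {
    stop_exposelect("not enough uncovered exposures to form the low block.",
                    "exposelect_calibration_error")
  }
  low_block <- sort(sample(uncov, 13L))
  list(family_labels = fam, high_block = high_block, low_block = low_block,
       clusters = clusters)
}

# Draw the raw (unscaled) structure. The model is hierarchical: exposures
# load on one latent entity each (their cluster factor, or themselves when
# unclustered), and the entities are correlated through family factors,
# cross-family "source" factors and a weak 3-dimensional background. A whole
# cluster therefore correlates with the rest of the exposome as a unit,
# which is what family-level exposure data look like in practice.
draw_loadings <- function(config, plan) {
  p <- config$p
  fam <- plan$family_labels
  is_low <- seq_len(p) %in% plan$low_block

  all_clusters <- c(list(plan$high_block), plan$clusters)
  n_cl <- length(all_clusters)
  unclustered <- setdiff(seq_len(p), unlist(all_clusters))
  n_ent <- n_cl + length(unclustered)

  # exposure -> entity map and within-entity loading h
  entity <- integer(p)
  h <- numeric(p)
  for (k in seq_len(n_cl)) {
    m <- all_clusters[[k]]
    entity[m] <- k
    h[m] <- if (k == 1L) stats::runif(length(m), 0.86, 0.905)
            else stats::runif(length(m), 0.82, 0.92)
  }
  entity[unclustered] <- n_cl + seq_along(unclustered)
  h[unclustered] <- 1

  # entity family membership: a cluster belongs to its members' family
  ent_fam <- integer(n_ent)
  for (k in seq_len(n_cl)) ent_fam[k] <- fam[all_clusters[[k]][1]]
  ent_fam[n_cl + seq_along(unclustered)] <- fam[unclustered]
  ent_low <- c(rep(FALSE, n_cl), is_low[unclustered])

  # entity variance budgets: each entity spends at most 0.58 of its unit
  # variance on shared factors, which bounds every cross-entity correlation
  # below the 0.6 partner threshold (only cluster mates are strong partners)
  cap <- ifelse(seq_len(n_ent) <= n_cl, 0.70, 0.58)
  budget <- cap * stats::runif(n_ent, 0.62, 1)
  budget[ent_low] <- 0.02
  mid_assign <- sample.int(config$n_mid_factors, n_ent, replace = TRUE)
  # background connectivity is hub-like (a few well-connected entities),
  # which widens the diffuse part of the correlation distribution
  raw <- list(fam = stats::runif(n_ent, 0.5, 1),
              mid = stats::runif(n_ent, 0.2, 1),
              bg = ifelse(stats::runif(n_ent) < 0.62, 1, 0.0625))
  W <- matrix(stats::rnorm(n_ent * 3L), n_ent, 3L)
  W <- W / sqrt(rowSums(W^2))

  list(entity = entity, h = h, n_ent = n_ent, ent_fam = ent_fam,
       ent_low = ent_low, budget = budget, mid_assign = mid_assign,
       raw = raw, bg_dir = W,
       n_families = config$n_families, n_mid = config$n_mid_factors)
}

# Assemble the exposure correlation matrix for given allocation weights.
# Each entity splits its shared-variance budget between its family factor,
# its source-profile factor and the 3-dimensional background according to
# the weights; the matrix is positive definite by construction.
assemble_sigma <- function(load, scales, plan, high_target) {
  w_fam <- 0.3 * load$raw$fam
  w_mid <- scales[["mid"]] * load$raw$mid
  w_bg <- scales[["bg"]] * load$raw$bg
  tot <- w_fam + w_mid + w_bg
  n_ent <- load$n_ent
  A_fam <- matrix(0, n_ent, load$n_families)
  A_fam[cbind(seq_len(n_ent), load$ent_fam)] <-
    sqrt(load$budget * w_fam / tot)
  A_mid <- matrix(0, n_ent, load$n_mid)
  A_mid[cbind(seq_len(n_ent), load$mid_assign)] <-
    sqrt(load$budget * w_mid / tot)
  A_bg <- load$bg_dir * sqrt(load$budget * w_bg / tot)
  A <- cbind(A_fam, A_mid, A_bg)
  B <- tcrossprod(A)
  diag(B) <- 1

  # high-block loadings rescaled so the block mean pairwise r is exact
  h <- load$h
  hb <- plan$high_block
  hh <- h[hb] %o% h[hb]
  h[hb] <- h[hb] * sqrt(high_target / mean(hh[upper.tri(hh)]))

  S <- (h %o% h) * B[load$entity, load$entity]
  diag(S) <- 1
  S
}

off_diag_abs <- function(M) abs(M[upper.tri(M)])

#' Summarize the off-diagonal correlation structure of a model
#'
#' Computes, over the `p(p-1)/2` off-diagonal entries: the fraction of
#' absolute correlations below each threshold, the median and selected
#' percentiles of the absolute correlations, and the fraction of exposures
#' having at least one partner above `partner_threshold`.
#'
#' @param model A `correlation_model` (or a bare correlation matrix).
#' @param thresholds Absolute-correlation thresholds for the "fraction
#'   below" summaries.
#' @param partner_threshold Threshold defining a highly correlated partner.
#' @param probs Percentiles of the absolute correlations to report.
#' @return A one-row tibble.
#' @export
summarize_correlations <- function(model, thresholds = c(0.1, 0.2),
                                   partner_threshold = 0.6,
                                   probs = c(0.025, 0.25, 0.75, 0.975)) {
  M <- if (inherits(model, "correlation_model")) model$matrix else model
  a <- off_diag_abs(M)
  A <- abs(M); diag(A) <- 0
  out <- tibble::tibble(median_abs = stats::median(a),
                        partner_frac = mean(apply(A, 1, max) > partner_threshold))
  for (th in thresholds) {
    out[[sprintf("frac_below_%g", th)]] <- mean(a < th)
  }
  q <- stats::quantile(a, probs = probs, names = FALSE)
  for (i in seq_along(probs)) {
    out[[sprintf("pctl_%g", 100 * probs[i])]] <- q[i]
  }
  if (inherits(model, "correlation_model") && !is.null(model$high_block)) {
    sub <- M[model$high_block, model$high_block]
    out$high_block_mean <- mean(sub[upper.tri(sub)])
  }
  out
}

#' Build a calibrated synthetic exposome correlation model
#'
#' Constructs a `p x p` correlation matrix from a layered factor model
#' (within-family clusters of highly correlated exposures, family factors,
#' cross-family source factors, and a weak isotropic background), then tunes
#' the background and source loading scales until the published summary
#' statistics of the target exposome are matched: the fractions of absolute
#' pairwise correlations below 0.2 and 0.1, the median absolute correlation,
#' and the fraction of exposures with a partner above 0.6. The matrix is
#' positive definite by construction (factor loadings plus positive
#' uniqueness), so no eigenvalue repair is needed for generated models.
#'
#' @param config A [generator_config()].
#' @param max_retries Structure redraws allowed before giving up.
#' @return A `correlation_model` with fields `matrix`, `family_labels`,
#'   `high_block`, `low_block`.
#' @export
build_correlation_model <- function(config = generator_config(),
                                    max_retries = 4L) {
  stopifnot(inherits(config, "generator_config"))
  if (config$independent) {
    fam <- rep(seq_along(config$family_sizes), config$family_sizes)
    return(new_correlation_model(diag(config$p), fam, NULL, NULL))
  }
  ts <- config$target_stats
  for (attempt in seq_len(max_retries + 1L)) {
    model <- with_seed(derive_seed(config$seed, "structure", attempt), {
      plan <- plan_structure(config)
      load <- draw_loadings(config, plan)
      scales <- config$scales
      S <- NULL
      for (it in 1:15) {
        S <- assemble_sigma(load, scales, plan, ts$high_block_mean)
        a <- off_diag_abs(S)
        # background drives the diffuse bulk (median), the cross-family
        # source factors drive the moderate band (fraction below 0.2)
        med <- stats::median(a)
        scales[["bg"]] <- scales[["bg"]] * (ts$median_abs / max(med, 1e-4))
        f2 <- mean(a < 0.2)
        scales[["mid"]] <- scales[["mid"]] * (1 + 1.5 * (f2 - ts$frac_below_0.2))
        scales[["bg"]] <- min(max(scales[["bg"]], 0.05), 8)
        scales[["mid"]] <- min(max(scales[["mid"]], 0.05), 8)
      }
      # enforce the low block strictly
      lb <- plan$low_block
      sub <- abs(S[lb, lb]); diag(sub) <- 0
      if (max(sub) > 0.095) {
        load$L_bg[lb, ] <- load$L_bg[lb, ] * sqrt(0.095 / max(sub))
        S <- assemble_sigma(load, scales, plan, ts$high_block_mean)
      }
      new_correlation_model(S, plan$family_labels, plan$high_block,
                            plan$low_block, plan$clusters)
    })
    viol <- calibration_violations(model, ts)
    if (length(viol) == 0L) {
      validate_correlation_model(model)
      return(model)
    }
    if (attempt == max_retries + 1L) {
      stop_exposelect(paste0("calibration failed after ", max_retries + 1L,
                             " attempts; violated target(s): ",
                             paste(viol, collapse = ", ")),
                      "exposelect_calibration_error")
    }
  }
}

calibration_violations <- function(model, ts) {
  s <- summarize_correlations(model,
                              partner_threshold = ts$partner_threshold)
  viol <- character(0)
  if (abs(s$`frac_below_0.2` - ts$frac_below_0.2) > 0.03) {
    viol <- c(viol, "frac_below_0.2")
  }
  if (abs(s$`frac_below_0.1` - ts$frac_below_0.1) > 0.03) {
    viol <- c(viol, "frac_below_0.1")
  }
  if (abs(s$median_abs - ts$median_abs) > 0.02) viol <- c(viol, "median_abs")
  if (abs(s$partner_frac - ts$partner_frac) > 0.03) {
    viol <- c(viol, "partner_frac")
  }
  if (abs(s$high_block_mean - ts$high_block_mean) > 0.02) {
    viol <- c(viol, "high_block_mean")
  }
  M <- model$matrix
  hb <- abs(M[model$high_block, model$high_block])
  if (min(hb[upper.tri(hb)]) < 0.62) viol <- c(viol, "high_block_min")
  lb <- abs(M[model$low_block, model$low_block])
  if (max(lb[upper.tri(lb)]) > 0.1) viol <- c(viol, "low_block_max")
  viol
}

#' Repair a symmetric matrix to the nearest unit-diagonal PSD matrix
#'
#' Alternates eigenvalue clipping at zero with restoring the unit diagonal
#' until convergence; this is the standard alternating-projections
#' approximation to the nearest correlation matrix in Frobenius distance.
#' Off-diagonal entries outside `[-1, 1]` are clipped first.
#'
#' @param M Symmetric matrix with unit diagonal (approximately).
#' @param tol Convergence tolerance on the smallest eigenvalue and on the
#'   iteration-to-iteration change.
#' @param max_iter Iteration cap.
#' @return A symmetric positive semi-definite matrix with unit diagonal.
#' @export
nearest_positive_definite <- function(M, tol = 1e-6, max_iter = 100L) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8) {
    stop_exposelect("`M` must be a symmetric square matrix.",
                    "exposelect_model_error")
  }
  X <- (M + t(M)) / 2
  X[X > 1] <- 1; X[X < -1] <- -1
  diag(X) <- 1
  for (i in seq_len(max_iter)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= -tol && i > 1L) break
    ev <- pmax(e$values, 0)
    Y <- e$vectors %*% (ev * t(e$vectors))
    Y <- (Y + t(Y)) / 2
    Y[Y > 1] <- 1; Y[Y < -1] <- -1
    diag(Y) <- 1
    if (max(abs(Y - X)) < tol && min(eigen(Y, symmetric = TRUE,
                                           only.values = TRUE)$values) >= -tol) {
      X <- Y
      break
    }
    X <- Y
  }
  e <- eigen(X, symmetric = TRUE, only.values = TRUE)
  if (min(e$values) < -tol) {
    ev <- eigen(X, symmetric = TRUE)
    X <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
    d <- sqrt(pmax(diag(X), .Machine$double.eps))
    X <- X / (d %o% d)
    diag(X) <- 1
    X <- (X + t(X)) / 2
  }
  X
}

#' Simulate standardized exposures from a correlation model
#'
#' Draws `n` independent rows from the mean-zero multivariate normal with
#' the model's correlation matrix.
#'
#' @param model A `correlation_model`.
#' @param n Number of participants (rows); at least 2.
#' @param seed Integer seed; same seed, same matrix.
#' @return A tibble with `n` rows and one column per exposure.
#' @export
simulate_exposures <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "correlation_model"), n >= 2)
  M <- model$matrix
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    ev <- eigen(M, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      stop_exposelect("model matrix is not PSD; repair it with nearest_positive_definite().",
                      "exposelect_model_error")
    }
    R <- t(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)))
  }
  E <- with_seed(seed, matrix(stats::rnorm(n * nrow(M)), n, nrow(M)) %*% R)
  colnames(E) <- model$exposure_ids
  tibble::as_tibble(E)
}

#' Write / read a correlation model as delimited text
#'
#' The matrix travels as a TSV with exposure ids in the header and first
#' column; families and block memberships travel in a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param model A `correlation_model`.
#' @param path Path of the matrix TSV.
#' @return `path`, invisibly (writer); a `correlation_model` (reader).
#' @export
write_correlation_model <- function(model, path) {
  df <- data.frame(id = model$exposure_ids, model$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(family_labels = model$family_labels,
               high_block = model$high_block, low_block = model$low_block)
  jsonlite::write_json(meta, paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_correlation_model
#' @export
read_correlation_model <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$id
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else list(family_labels = rep(1L, nrow(M)))
  model <- new_correlation_model(M, meta$family_labels,
                                 meta$high_block, meta$low_block)
  validate_correlation_model(model)
}
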