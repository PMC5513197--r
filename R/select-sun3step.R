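#' Configuration for the three-step screen/tree/search selector
#'
#' @param r_threshold Within-family absolute Pearson correlation above which
#'   exposures are grouped in the screening step.
#' @param tree_cv_folds Cross-validation folds used when pruning the
#'   regression tree.
#' @param dsa_config Configuration of the final search step (order 2, so
#'   quadratics and pairwise interactions are searched).
#' @param seed Integer seed (tree cross-validation).
#' @return A list of class `sun3step_config`.
#' @export
sun3step_config <- function(r_threshold = 0.60, tree_cv_folds = 10L,
                            dsa_config = NULL, seed = 1L) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  dsa_config <- dsa_config %||% make_dsa2_config()
  structure(list(r_threshold = r_threshold,
                 tree_cv_folds = as.integer(tree_cv_folds),
                 dsa_config = dsa_config, seed = as.integer(seed)),
            class = "sun3step_config")
}

# connected components of an undirected adjacency matrix (logical)
adjacency_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Three-step selector: correlation screen, regression tree, DSA search
#'
#' Step 1 groups, within each exposure family, the exposures whose pairwise
#' absolute sample correlation exceeds `r_threshold` (connected components
#' of the threshold graph) and keeps from each group only the exposure with
#' the smallest marginal p-value; ungrouped exposures all pass. Step 2 fits
#' a regression tree on the survivors and prunes it to the subtree with the
#' smallest cross-validated error; the variables used in any split pass.
#' Step 3 runs the deletion/substitution/addition search (order 2) on those
#' variables; its output is the final model. A tree with no splits yields
#' an empty selection.
#'
#' @param data Data frame with exposures and the outcome column.
#' @param outcome Name of the outcome column.
#' @param families Integer vector of family labels, one per exposure column
#'   (in column order).
#' @param config A [sun3step_config()].
#' @return A `selected_model`.
#' @export
sun3step <- function(data, outcome = "y", families,
                     config = sun3step_config()) {
  d <- split_exposures(data, outcome)
  E <- d$E; y <- d$y
  p <- ncol(E)
  if (length(families) != p) {
    stop_exposelect("`families` must label every exposure column.",
                    "exposelect_config_error")
  }

  # step 1: within-family correlation screen
  pvals <- marginal_pvalues(E, y)
  keep <- logical(p)
  for (f in unique(families)) {
    m <- which(families == f)
    if (length(m) == 1L) { keep[m] <- TRUE; next }
    r <- abs(stats::cor(E[, m, drop = FALSE]))
    adj <- r > config$r_threshold
    diag(adj) <- FALSE
    comp <- adjacency_components(adj)
    for (g in unique(comp)) {
      members <- m[comp == g]
      keep[members[which.min(pvals[members])]] <- TRUE
    }
  }
  survivors <- which(keep)

  # step 2: pruned regression tree on survivors
  df <- data.frame(E[, survivors, drop = FALSE])
  names(df) <- paste0("V", survivors)
  df$.y <- y
  tree <- with_seed(config$seed,
    rpart::rpart(.y ~ ., data = df, method = "anova",
                 control = rpart::rpart.control(cp = 1e-3,
                                                xval = config$tree_cv_folds)))
  cp_tab <- tree$cptable
  best_cp <- cp_tab[which.min(cp_tab[, "xerror"]), "CP"]
  pruned <- rpart::prune(tree, cp = best_cp)
  used <- unique(as.character(pruned$frame$var))
  used <- used[used != "<leaf>"]
  tree_vars <- sort(as.integer(sub("^V", "", used)))

  if (length(tree_vars) == 0L) {
    return(selected_model("Sun3step", NULL, intercept = mean(y),
                          predict_fn = local({
                            mu <- mean(y)
                            function(Enew) rep(mu, nrow(as.matrix(Enew)))
                          }),
                          info = list(survivors = survivors,
                                      tree_vars = integer(0))))
  }

  # step 3: order-2 DSA restricted to the tree variables
  sub <- data.frame(E[, tree_vars, drop = FALSE])
  names(sub) <- paste0("x", seq_along(tree_vars))
  sub$.y <- y
  fit <- dsa(sub, outcome = ".y", config = config$dsa_config)

  # map term indices back to the original exposure columns
  terms <- fit$terms
  terms$i <- tree_vars[terms$i]
  terms$j <- ifelse(is.na(terms$j), NA_integer_, tree_vars[terms$j])
  inner_predict <- fit$predict_fn
  predict_fn <- local({
    tv <- tree_vars; pf <- inner_predict
    function(Enew) pf(as.matrix(Enew)[, tv, drop = FALSE])
  })
  coefs <- fit$coefficients
  if (!is.null(coefs)) {
    # tree_vars is ascending, so the remap preserves i < j and term labels
    # can simply be recomputed on the remapped terms
    names(coefs) <- term_labels(terms)
  }
  selected_model("Sun3step", terms, coefficients = coefs,
                 intercept = fit$intercept, predict_fn = predict_fn,
                 info = list(survivors = survivors, tree_vars = tree_vars,
                             dsa_info = fit$info))
}
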