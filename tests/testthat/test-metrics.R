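# study whose exposures come from the proxy-pair model: exposures 1..5 are
# the true predictors, 6..10 their 0.9-correlated proxies
proxy_study <- function(scenario_id = "1a", n_train = 60, n_valid = 80) {
  m <- proxy_pair_model(5, 0.9)
  spec <- scenario_spec(scenario_id)
  pred <- 1:5
  tm <- make_true_model(spec, pred)
  E_tr <- simulate_exposures(m, n_train, seed = 1)
  E_va <- simulate_exposures(m, n_valid, seed = 2)
  list(model = m,
       study = structure(list(train = E_tr,
                              y_train = simulate_outcome(E_tr, tm, seed = 3),
                              valid = E_va,
                              y_valid = simulate_outcome(E_va, tm, seed = 4),
                              true_model = tm, spec = spec, seed = 1),
                         class = "simulated_study"))
}

ols_refit_model <- function(method, terms, study, ...) {
  fit <- ols_fit(study$train, study$y_train, terms)
  co <- fit$tidy$estimate
  selected_model(method, terms,
                 predict_fn = function(Enew)
                   drop(cbind(1, design_columns(Enew, canonical_terms(terms))) %*% co),
                 ...)
}

test_that("proxies count for the alternative measures but not the exact ones", {
  px <- proxy_study()
  # fitted model = the five proxies, none a true predictor, each correlated
  # 0.9 with exactly one true predictor
  sel <- ols_refit_model("DSA1", purrr::map_dfr(6:10, term_main), px$study,
                         searches_interactions = FALSE)
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$alt_sens, 0.9)
  expect_equal(ev$sens, 0)
  expect_equal(ev$sens_var, 0)
  expect_equal(ev$alt_fdp, 0.1)
  expect_equal(ev$fdp_var, 1)
  expect_equal(ev$fdp, 1)
})

test_that("the true model evaluates to perfect scores", {
  px <- proxy_study("2e")
  tt <- true_terms(px$study$true_model)
  sel <- ols_refit_model("DSA2", tt, px$study)
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$rms, 1)
  expect_equal(ev$rnv, 1)
  expect_equal(ev$sens, 1)
  expect_equal(ev$sens_var, 1)
  expect_equal(ev$sens2, 1)
  expect_equal(ev$alt_sens, 1)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$fdp_var, 0)
  expect_equal(ev$fdp2, 0)
  expect_equal(ev$alt_fdp, 0)
  expect_equal(ev$r2_rel, 1, tolerance = 1e-8)
})

test_that("the empty selection is scored per the conventions", {
  px <- proxy_study("1b", n_train = 400, n_valid = 500)
  sel <- selected_model("DSA1", NULL, searches_interactions = FALSE,
                        predict_fn = local({
                          mu <- mean(px$study$y_train)
                          function(Enew) rep(mu, nrow(as.matrix(Enew)))
                        }))
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$rms, 0)
  expect_equal(ev$rnv, 0)
  expect_equal(ev$sens, 0)
  expect_equal(ev$fdp, 0)
  expect_equal(ev$fdp_var, 0)
  expect_true(is.na(ev$alt_sens))
  expect_true(is.na(ev$alt_fdp))
  expect_true(ev$empty_model)
  expect_equal(ev$r2_rel, 0, tolerance = 0.05)
})

test_that("counting follows the worked size example and quads are false
           terms with true variables", {
  px <- proxy_study()          # scenario 1: five true terms, five variables
  terms <- dplyr::bind_rows(term_main(1), term_main(2), term_quad(1),
                            term_inter(1, 2))
  sel <- ols_refit_model("DSA2", terms, px$study)
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$rms, 4 / 5)
  expect_equal(ev$rnv, 2 / 5)
  # mains 1, 2 are true; the quad and the interaction are false terms
  expect_equal(ev$sens, 2 / 5)
  expect_equal(ev$fdp, 2 / 4)
  expect_equal(ev$fdp_var, 0)
  expect_equal(ev$sens_var, 2 / 5)
})

test_that("scenario-2 truth scored against a mains-only selection", {
  px <- proxy_study("2e")
  sel <- ols_refit_model("DSA2", purrr::map_dfr(1:5, term_main), px$study)
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$sens, 5 / 6)
  expect_equal(ev$sens2, 0)
  expect_equal(ev$sens_var, 1)
  expect_true(is.na(ev$alt_sens2))  # no fitted interaction variables
})

test_that("interaction matching is unordered", {
  px <- proxy_study("2e")      # true interaction is X1 X2 = exposures 1, 2
  sel <- ols_refit_model("DSA2", dplyr::bind_rows(term_inter(2, 1)),
                         px$study)
  ev <- evaluate_selection(sel, px$study, px$model)
  expect_equal(ev$sens2, 1)
  expect_equal(ev$fdp2, 0)
})

test_that("capability flags gate the measures as in the availability table", {
  px <- proxy_study("2e")
  terms <- purrr::map_dfr(1:3, term_main)
  # EWAS2-like: no single model, no predictions
  ev_e <- evaluate_selection(
    selected_model("EWAS2", terms, has_single_model = FALSE,
                   predicts = FALSE), px$study, px$model)
  expect_true(is.na(ev_e$r2_rel))
  expect_false(is.na(ev_e$rms))
  expect_false(is.na(ev_e$sens2))
  # LASSO-like: no interaction search
  ev_l <- evaluate_selection(
    ols_refit_model("LASSO", terms, px$study,
                    searches_interactions = FALSE), px$study, px$model)
  expect_true(is.na(ev_l$sens2))
  expect_true(is.na(ev_l$fdp2))
  expect_false(is.na(ev_l$r2_rel))
  # BRT-like: variables only
  ev_b <- evaluate_selection(
    ols_refit_model("BRT", terms, px$study, term_level = FALSE,
                    searches_interactions = FALSE), px$study, px$model)
  expect_true(is.na(ev_b$rms))
  expect_true(is.na(ev_b$sens))
  expect_true(is.na(ev_b$fdp))
  expect_false(is.na(ev_b$rnv))
  expect_false(is.na(ev_b$alt_sens))
  expect_false(is.na(ev_b$fdp_var))
})

test_that("alt_sens dominates sens and alt_fdp is below fdp_var on random
           selections over a correlated exposome", {
  m <- cached_default_model(1)
  spec <- scenario_spec("1c")
  set.seed(10)
  for (r in 1:20) {
    tm <- make_true_model(spec, select_true_predictors(m, "high", seed = r))
    sel <- selected_model("DSA1",
                          purrr::map_dfr(sample(237, sample(3:8, 1)),
                                         term_main),
                          searches_interactions = FALSE)
    study <- list(true_model = tm)
    cmp <- selection_comparison(sel, tm)
    R <- abs(m$matrix)
    alt_sens <- exposelect:::avg_max_abs_corr(R, cmp$A, cmp$B)
    sens <- length(intersect(cmp$A, cmp$B)) / 5
    alt_fdp <- 1 - exposelect:::avg_max_abs_corr(R, cmp$B, cmp$A)
    fdp_var <- length(setdiff(cmp$B, cmp$A)) / length(cmp$B)
    expect_gte(alt_sens, sens)
    expect_lte(alt_fdp, fdp_var)
  }
})

test_that("measures are invariant to exposure relabeling", {
  px <- proxy_study("2e")
  terms <- dplyr::bind_rows(term_main(1), term_main(6), term_inter(1, 2))
  sel <- ols_refit_model("DSA2", terms, px$study)
  ev <- evaluate_selection(sel, px$study, px$model)

  # relabel exposures by a permutation applied consistently everywhere
  perm <- sample(10)
  inv <- order(perm)
  m2 <- correlation_model(px$model$matrix[inv, inv])
  st2 <- px$study
  st2$train <- px$study$train[, inv]
  st2$valid <- px$study$valid[, inv]
  tm2 <- st2$true_model
  tm2$predictor_indices <- perm[tm2$predictor_indices]
  tm2$gammas$i <- perm[tm2$gammas$i]
  tm2$gammas$j <- perm[tm2$gammas$j]
  swap <- tm2$gammas$i > tm2$gammas$j
  tmp <- tm2$gammas$i[swap]
  tm2$gammas$i[swap] <- tm2$gammas$j[swap]
  tm2$gammas$j[swap] <- tmp
  st2$true_model <- tm2
  terms2 <- dplyr::bind_rows(term_main(perm[1]), term_main(perm[6]),
                             term_inter(perm[1], perm[2]))
  sel2 <- ols_refit_model("DSA2", terms2, st2)
  ev2 <- evaluate_selection(sel2, st2, m2)
  for (mcol in c("rms", "rnv", "sens", "sens_var", "sens2", "alt_sens",
                 "fdp", "fdp_var", "fdp2", "alt_fdp")) {
    expect_equal(ev2[[mcol]], ev[[mcol]], tolerance = 1e-10)
  }
})
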