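test_that("the scenario registry encodes the design constraints", {
  reg <- scenario_registry()
  expect_equal(nrow(reg), 21)
  expect_setequal(reg$scenario_id[reg$scenario == 1], c("1a", "1b", "1c", "1d"))
  strong <- reg[reg$interaction_size == "strong", ]
  expect_true(all(abs(strong$gamma12) == 1))
  moderate <- reg[reg$interaction_size == "moderate", ]
  expect_true(all(abs(moderate$gamma12) == 0.5))
  expect_true(all(reg$gamma12[reg$scenario == 1] == 0))
  expect_true(all(reg$gamma13[reg$scenario <= 2] == 0))
  expect_true(all(reg$sigma > 0, na.rm = TRUE))
  expect_equal(reg$model_size, 5L + reg$n_interactions)
  expect_error(scenario_spec("9z"), class = "exposelect_config_error")
})

test_that("predictor draws respect the correlation mode", {
  m <- cached_default_model(1)
  ph <- select_true_predictors(m, "high", seed = 4)
  expect_length(ph, 5)
  sub <- abs(m$matrix[ph, ph])
  expect_gte(min(sub[upper.tri(sub)]), 0.62)
  pl <- select_true_predictors(m, "low", seed = 4)
  subl <- abs(m$matrix[pl, pl])
  expect_lte(max(subl[upper.tri(subl)]), 0.1)
  # p = 5 pool is forced
  toy <- equi_model(5, 0.3)
  expect_setequal(select_true_predictors(toy, "mixed", seed = 1), 1:5)
  expect_error(select_true_predictors(toy, "high"),
               class = "exposelect_config_error")
  # reproducibility
  expect_identical(select_true_predictors(m, "mixed", seed = 9),
                   select_true_predictors(m, "mixed", seed = 9))
})

test_that("repeated high-mode draws concentrate on the block calibration", {
  m <- cached_default_model(1)
  means <- vapply(1:300, function(r) {
    idx <- select_true_predictors(m, "high", seed = r)
    sub <- m$matrix[idx, idx]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  expect_lt(abs(median(means) - 0.78), 0.03)
})

test_that("true models attach interactions to the first drawn predictors", {
  pred <- c(30, 7, 101, 4, 55)
  tm2e <- make_true_model(scenario_spec("2e"), pred)
  expect_equal(nrow(tm2e$gammas), 1)
  expect_equal(tm2e$gammas$gamma, 1)
  expect_setequal(c(tm2e$gammas$i, tm2e$gammas$j), c(30, 7))

  tm1a <- make_true_model(scenario_spec("1a"), pred)
  expect_equal(nrow(tm1a$gammas), 0)
  expect_equal(count_terms(true_terms(tm1a)), 5)

  tm3h <- make_true_model(scenario_spec("3h"), pred)
  expect_equal(nrow(tm3h$gammas), 2)
  expect_true(all(tm3h$gammas$gamma == -0.5))
  shared <- intersect(c(tm3h$gammas$i[1], tm3h$gammas$j[1]),
                      c(tm3h$gammas$i[2], tm3h$gammas$j[2]))
  expect_equal(shared, 30)  # X1 is in both pairs
  expect_equal(count_terms(true_terms(tm3h)), 7)
})

test_that("outcomes are exact in the noise-free limit and seeded", {
  toy <- equi_model(6, 0.2)
  E <- simulate_exposures(toy, 100, seed = 2)
  spec <- spec_with("2e", sigma = 1e-12)
  tm <- make_true_model(spec, 1:5)
  y <- simulate_outcome(E, tm, seed = 5)
  Em <- as.matrix(E)
  f <- 1 + rowSums(Em[, 1:5]) + Em[, 1] * Em[, 2]
  expect_equal(y, f, tolerance = 1e-8)
  tm2 <- make_true_model(scenario_spec("2e"), 1:5)
  expect_identical(simulate_outcome(E, tm2, seed = 5),
                   simulate_outcome(E, tm2, seed = 5))
})

test_that("the outcome is linear in the coefficients at sigma = 0", {
  toy <- equi_model(6, 0.2)
  E <- simulate_exposures(toy, 50, seed = 3)
  tm <- make_true_model(spec_with("3g", sigma = 1e-300), 1:5)
  y1 <- simulate_outcome(E, tm, seed = 1)
  tm_double <- tm
  tm_double$betas <- 2 * tm$betas
  tm_double$gammas$gamma <- 2 * tm$gammas$gamma
  y2 <- simulate_outcome(E, tm_double, seed = 1)
  expect_equal(y2 - tm$beta0, 2 * (y1 - tm$beta0), tolerance = 1e-9)
})

test_that("expected_r2 reproduces the Isserlis closed forms", {
  # five equicorrelated (0.78) predictors, unit betas, sigma = 13:
  # Var(F) = 5 + 20 * 0.78 = 20.6 and R2 = 20.6 / (20.6 + 169)
  m5 <- equi_model(5, 0.78)
  r2 <- expected_r2(spec_with("1c", sigma = 13), m5, 1:5)
  expect_equal(r2, 20.6 / (20.6 + 169), tolerance = 1e-12)

  # independent predictors, sigma -> 0: R2 -> 1
  ind <- correlation_model(diag(5))
  expect_gt(expected_r2(spec_with("1a", sigma = 1e-8), ind, 1:5), 0.999999)

  # pure product of two independent normals has variance 1:
  # with gamma = 1 only and sigma = 1, R2 = 1 / (1 + 1)
  g <- tibble::tibble(i = 1L, j = 2L, gamma = 1)
  v <- exposelect:::var_true_signal(diag(2), integer(0), numeric(0), g)
  expect_equal(v, 1)

  # one strong interaction on the equicorrelated block (2e structure):
  # Var(F) = 20.6 + (1 + 0.78^2)
  r2e <- expected_r2(spec_with("2e", sigma = 12), m5, 1:5)
  expect_equal(r2e, 22.2084 / (22.2084 + 144), tolerance = 1e-10)
})

test_that("simulated outcome variance matches the closed form", {
  m5 <- equi_model(5, 0.78)
  spec <- scenario_spec("1c")
  tm <- make_true_model(spec, 1:5)
  E <- simulate_exposures(m5, 100000, seed = 21)
  y <- simulate_outcome(E, tm, seed = 22)
  v_theory <- 20.6 + 13^2
  expect_equal(var(y), v_theory, tolerance = 0.02)
})

test_that("calibrate_sigma inverts the R2 relation", {
  # algebraic identity on independent predictors: Var(F) = 5 for
  # scenario 1, so target 0.5 gives sigma = sqrt(5)
  ind <- correlation_model(diag(20))
  s <- calibrate_sigma(spec_with("1a", target_r2 = 0.5), ind,
                       target_r2 = 0.5)
  expect_equal(s, sqrt(5), tolerance = 1e-10)

  # the high block reproduces the published noise levels
  m <- cached_default_model(1)
  s1c <- calibrate_sigma(scenario_spec("1c"), m)
  expect_equal(s1c, 13, tolerance = 0.05)
  s2e <- calibrate_sigma(scenario_spec("2e"), m)
  expect_equal(s2e, 12, tolerance = 0.05)
})

test_that("true-model sensitivity matches power calculations", {
  ind_cfg <- correlation_model(diag(30))
  # near-zero noise: every term significant
  s0 <- true_model_sensitivity(spec_with("1a", sigma = 1e-6), ind_cfg,
                               n_reps = 3, n = 200, seed = 2)
  expect_equal(s0, 1)
  # sigma chosen for per-term power 0.9 via the normal approximation to
  # the noncentral t: ncp = qnorm(0.975) + qnorm(0.9)
  sigma_power <- sqrt(1200) / (qnorm(0.975) + qnorm(0.9))
  s9 <- true_model_sensitivity(spec_with("1a", sigma = sigma_power),
                               ind_cfg, n_reps = 40, n = 1200, seed = 3)
  expect_equal(s9, 0.9, tolerance = 0.05)
})

test_that("empirical adjusted R2 tracks the closed form per subscenario", {
  m <- cached_default_model(1)
  for (sid in c("1c", "2g")) {
    spec <- scenario_spec(sid)
    vals <- vapply(1:25, function(r) {
      st <- simulate_study(spec, m, seed = r, n_valid = 10)
      fit <- ols_fit(st$train, st$y_train, true_terms(st$true_model))
      adjusted_r2(st$y_train, fit$fitted,
                  count_terms(true_terms(st$true_model)))
    }, numeric(1))
    theo <- mean(vapply(1:25, function(r) {
      expected_r2(spec, m, select_true_predictors(m, spec$correlation_mode,
                                                  seed = derive_seed(r, "pred")))
    }, numeric(1)))
    expect_equal(mean(vals), theo, tolerance = 0.035)
  }
})

test_that("the low-correlation subscenario calibrates its own sigma", {
  m <- cached_default_model(1)
  spec <- scenario_spec("2i")
  expect_true(is.na(spec$sigma))
  st <- simulate_study(spec, m, seed = 2, n_train = 100, n_valid = 50)
  expect_gt(st$true_model$sigma, 0)
  # predictors came from the low block
  expect_true(all(st$true_model$predictor_indices %in% m$low_block))
})
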