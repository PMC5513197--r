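test_that("lasso: null model beyond lambda_max, OLS at lambda -> 0", {
  dat <- toy_exposures(200, 5, seed = 1)
  set.seed(2)
  dat$y <- 2 * dat$e1 - dat$e3 + rnorm(200)
  d <- exposelect:::split_exposures(dat, "y")
  # beyond lambda_max every coefficient is zero
  lam_max <- max(abs(crossprod(scale(d$E), d$y - mean(d$y)))) / nrow(d$E)
  fit0 <- glmnet::glmnet(d$E, d$y, lambda = lam_max * 1.05)
  expect_equal(max(abs(as.matrix(fit0$beta))), 0)
  # tiny penalty recovers OLS
  des <- exposelect:::glint_design(d$E, d$y, NULL)
  L <- exposelect:::glint_lipschitz(des)
  f <- exposelect:::glint_fit_one(des, 1e-7, sqrt(3), rep(0, 5),
                                  matrix(0, 3, 0), L, 1e-11, 100000)
  ols <- qr.coef(qr(cbind(1, des$Xs)), des$yc)[-1]
  expect_equal(unname(f$alpha), unname(ols), tolerance = 1e-4)
})

test_that("lasso selection finds the active set with original-scale coefficients", {
  dat <- toy_exposures(300, 6, seed = 5)
  set.seed(6)
  dat$e2 <- dat$e2 * 3 + 1            # non-standardized column
  dat$y <- 2 * dat$e1 + 0.8 * dat$e2 + rnorm(300, 0, 0.5)
  s <- lasso_select(dat)
  expect_true(all(c(1, 2) %in% model_variables(s)))
  expect_false(s$searches_interactions)
  co <- s$coefficients
  expect_equal(unname(co["main:2"]), 0.8, tolerance = 0.1)
  pred <- s$predict_fn(dat[paste0("e", 1:6)])
  expect_gt(cor(pred, dat$y), 0.95)
})

test_that("orthonormal design gives the soft-threshold closed form", {
  set.seed(11)
  q <- qr.Q(qr(matrix(rnorm(200 * 5), 200, 5))) * sqrt(200)
  y <- rnorm(200)
  des <- list(Xs = q, P = matrix(0, 200, 0), yc = y, n = 200, pairs = NULL)
  b <- drop(crossprod(q, y)) / 200
  lam <- 0.06
  f <- exposelect:::glint_fit_one(des, lam, sqrt(3), rep(0, 5),
                                  matrix(0, 3, 0),
                                  exposelect:::glint_lipschitz(des),
                                  1e-11, 100000)
  expect_equal(f$alpha, sign(b) * pmax(abs(b) - lam, 0), tolerance = 1e-8)
})

test_that("group-lasso reduces to the lasso when interactions are disabled", {
  dat <- toy_exposures(250, 7, seed = 21)
  set.seed(22)
  dat$y <- 1.5 * dat$e1 - dat$e4 + rnorm(250)
  d <- exposelect:::split_exposures(dat, "y")
  des <- exposelect:::glint_design(d$E, d$y, NULL)
  L <- exposelect:::glint_lipschitz(des)
  for (lam in c(0.3, 0.1, 0.02)) {
    f <- exposelect:::glint_fit_one(des, lam, sqrt(3), rep(0, 7),
                                    matrix(0, 3, 0), L, 1e-11, 200000)
    g <- glmnet::glmnet(des$Xs, des$yc, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-13)
    expect_equal(unname(f$alpha), unname(as.vector(g$beta)),
                 tolerance = 1e-5)
  }
})

test_that("strong hierarchy holds on every selection", {
  for (seed in 1:4) {
    dat <- toy_exposures(250, 6, seed = 30 + seed)
    set.seed(40 + seed)
    dat$y <- dat$e1 + dat$e2 + 1.2 * dat$e1 * dat$e2 +
      0.5 * dat$e3 + rnorm(250, 0, 0.8)
    s <- glinternet_select(dat)
    inters <- s$terms[s$terms$kind == "inter", ]
    mains <- s$terms$i[s$terms$kind == "main"]
    if (nrow(inters) > 0) {
      expect_true(all(c(inters$i, inters$j) %in% mains))
    }
  }
})

test_that("a strong interaction with its mains is recovered at lambda*", {
  dat <- toy_exposures(400, 4, seed = 51)
  set.seed(52)
  dat$y <- dat$e1 + dat$e2 + dat$e1 * dat$e2 + rnorm(400, 0, 0.3)
  s <- glinternet_select(dat)
  labs <- exposelect:::term_labels(s$terms)
  expect_true(all(c("main:1", "main:2", "inter:1:2") %in% labs))
  # the true terms dominate the fitted coefficients
  co <- s$coefficients
  expect_equal(unname(co["inter:1:2"]), 1, tolerance = 0.15)
  expect_gt(cor(s$predict_fn(dat[paste0("e", 1:4)]), dat$y), 0.95)
})

test_that("KKT conditions hold at the solver optimum", {
  dat <- toy_exposures(150, 4, seed = 61)
  set.seed(62)
  dat$y <- dat$e1 - 0.5 * dat$e2 + rnorm(150, 0, 0.5)
  d <- exposelect:::split_exposures(dat, "y")
  pairs <- utils::combn(4, 2)
  des <- exposelect:::glint_design(d$E, d$y, pairs)
  w <- sqrt(3); lam <- 0.08; tol <- 1e-9
  f <- exposelect:::glint_fit_one(des, lam, w, rep(0, 4),
                                  matrix(0, 3, ncol(pairs)),
                                  exposelect:::glint_lipschitz(des),
                                  tol, 300000)
  r <- des$yc - exposelect:::glint_predict_std(des, f$alpha, f$theta)
  u <- drop(crossprod(des$Xs, r)) / des$n
  # singletons: |grad| <= lambda at zero, grad = lambda * sign at nonzero
  for (i in 1:4) {
    if (abs(f$alpha[i]) > 1e-8) {
      expect_equal(u[i], lam * sign(f$alpha[i]), tolerance = 1e-4)
    } else {
      expect_lte(abs(u[i]), lam + 1e-4)
    }
  }
  # groups: gradient norm <= w * lambda at zero groups
  v <- drop(crossprod(des$P, r)) / des$n
  for (g in seq_len(ncol(pairs))) {
    gn <- sqrt(u[pairs[1, g]]^2 + u[pairs[2, g]]^2 + v[g]^2)
    if (sqrt(sum(f$theta[, g]^2)) <= 1e-8) {
      expect_lte(gn, w * lam + 1e-3)
    }
  }
})

test_that("warm-started path solutions vary continuously in lambda", {
  dat <- toy_exposures(200, 5, seed = 71)
  set.seed(72)
  dat$y <- dat$e1 + 0.5 * dat$e2 + rnorm(200, 0, 0.5)
  d <- exposelect:::split_exposures(dat, "y")
  des <- exposelect:::glint_design(d$E, d$y, NULL)
  lam <- exp(seq(log(0.5), log(0.01), length.out = 30))
  path <- exposelect:::glint_path(des, lam, sqrt(3), 1e-9, 100000)
  alphas <- t(vapply(path, function(f) f$alpha, numeric(5)))
  jumps <- apply(abs(diff(alphas)), 1, max)
  expect_lt(max(jumps), 0.15)
})

test_that("the shared CV engine reproduces leave-one-out OLS residuals", {
  set.seed(81)
  n <- 12
  dat <- toy_exposures(n, 2, seed = 81)
  dat$y <- dat$e1 + rnorm(n, 0, 0.4)
  ols_fitter <- function(Etr, ytr, lambda) {
    co <- qr.coef(qr(cbind(1, Etr)), ytr)
    function(Ete) matrix(cbind(1, Ete) %*% co, ncol = length(lambda))
  }
  out <- cv_curve(dat, "y", ols_fitter, lambda = 0,
                  config = penalized_config(folds = n))
  X <- cbind(1, as.matrix(dat[c("e1", "e2")]))
  H <- X %*% solve(crossprod(X), t(X))
  e <- dat$y - X %*% solve(crossprod(X), crossprod(X, dat$y))
  loo <- (e / (1 - diag(H)))^2
  expect_equal(out$curve$mean_error, mean(loo), tolerance = 1e-10)
})

test_that("cv error is near zero for a noiseless signal and the null
           lambda wins on pure noise", {
  dat <- toy_exposures(120, 3, seed = 91)
  dat$y <- dat$e1 + dat$e2
  s <- glinternet_select(dat, config = penalized_config(seed = 1))
  expect_lt(min(s$info$cv_mean), 1e-3)
  hits <- vapply(1:5, function(seed) {
    nd <- toy_exposures(100, 4, seed = 200 + seed)
    set.seed(300 + seed)
    nd$y <- rnorm(100)
    sn <- glinternet_select(nd, config = penalized_config(seed = seed))
    which.min(sn$info$cv_mean)
  }, numeric(1))
  expect_lte(median(hits), 6)   # minimum at or near the null end
})
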