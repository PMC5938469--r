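sar_testbed <- function(n_side = 10, seed = 1, thr = 15) {
  co <- grid_coords(n_side, n_side)
  w <- build_weights(co, threshold_km = thr)
  X <- withr::with_seed(seed, cbind(1, x1 = stats::rnorm(n_side^2),
                                    x2 = stats::rnorm(n_side^2)))
  list(w = w, X = X)
}

test_that("lambda fixed at zero reproduces ordinary least squares exactly", {
  tb <- sar_testbed()
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0, 1, seed = 10)
  f0 <- fit_sar_error(y, tb$X, tb$w, fix_lambda = 0)
  ols <- stats::lm(y ~ x1 + x2, data = data.frame(y = y, tb$X[, 2:3]))
  expect_equal(unname(f0$coefficients$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f0$loglik, as.numeric(stats::logLik(ols)), tolerance = 1e-8)
  expect_equal(f0$residuals, f0$whitened_residuals)
})

test_that("log-likelihood matches a direct multivariate-normal evaluation", {
  tb <- sar_testbed(n_side = 5, seed = 2)
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.5, 1, seed = 20)
  f <- fit_sar_error(y, tb$X, tb$w)
  n <- tb$w$n
  A <- diag(n) - f$lambda * tb$w$W
  Sigma <- f$sigma2 * solve(crossprod(A))
  r <- y - drop(tb$X %*% f$coefficients$beta)
  ll_direct <- -n / 2 * log(2 * pi) -
    0.5 * determinant(Sigma, logarithm = TRUE)$modulus -
    0.5 * drop(crossprod(r, solve(Sigma, r)))
  expect_equal(f$loglik, as.numeric(ll_direct), tolerance = 1e-6)
})

test_that("profile optimum dominates the nested OLS point", {
  tb <- sar_testbed(seed = 3)
  for (s in 1:5) {
    y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.4, 1, seed = 30 + s)
    f <- fit_sar_error(y, tb$X, tb$w)
    f0 <- fit_sar_error(y, tb$X, tb$w, fix_lambda = 0)
    expect_gte(f$loglik, f0$loglik - 1e-8)
  }
})

test_that("Nagelkerke pseudo-R2 is zero at the null and grows with likelihood", {
  tb <- sar_testbed(seed = 4)
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0, 1, seed = 44)
  null_fit <- fit_sar_error(y, matrix(1, tb$w$n, 1), tb$w, fix_lambda = 0)
  expect_equal(null_fit$nagelkerke_r2, 0, tolerance = 1e-10)
  f1 <- fit_sar_error(y, tb$X[, 1:2], tb$w, fix_lambda = 0)
  f2 <- fit_sar_error(y, tb$X, tb$w, fix_lambda = 0)
  expect_gt(f2$loglik, f1$loglik)
  expect_gt(f2$nagelkerke_r2, f1$nagelkerke_r2)
})

test_that("squared-response transform is applied and recorded", {
  tb <- sar_testbed(seed = 5)
  y <- abs(gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0, 1, seed = 50))
  fs <- fit_sar_error(y, tb$X, tb$w, transform = "square", fix_lambda = 0)
  fm <- fit_sar_error(y^2, tb$X, tb$w, transform = "identity", fix_lambda = 0)
  expect_equal(fs$coefficients$beta, fm$coefficients$beta, tolerance = 1e-12)
  expect_equal(fs$transform, "square")
})

test_that("singular designs are rejected", {
  tb <- sar_testbed(seed = 6)
  X <- cbind(tb$X, dup = tb$X[, 2])
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0, 1, seed = 60)
  expect_error(fit_sar_error(y, X, tb$w), "singular")
})

test_that("likelihood-ratio test identities hold", {
  tb <- sar_testbed(seed = 7)
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.4, 1, seed = 70)
  full <- fit_sar_error(y, tb$X, tb$w)
  same <- lr_test(full, full)
  expect_equal(same$lr, 0)
  expect_equal(same$p_value, 1)
  red <- fit_sar_error(y, tb$X[, 1:2], tb$w)
  lt <- lr_test(full, red)
  expect_equal(lt$df, 1L)
  # LR = -(AIC_full - AIC_reduced) + 2 df
  expect_equal(lt$lr, -(full$aic - red$aic) + 2 * lt$df, tolerance = 1e-10)
  # chi-square quantile: LR 3.84 on 1 df sits at p ~ 0.050
  expect_equal(stats::pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(lr_test(red, full), "not nested")
})

test_that("backward elimination drops noise and honours protection", {
  tb <- sar_testbed(seed = 8)
  # a pure-noise column is eliminated in the vast majority of replicates
  # (retention is a 5% false-positive event by construction)
  dropped <- vapply(1:15, function(s) {
    noise <- withr::with_seed(800 + s, stats::rnorm(tb$w$n))
    X <- cbind(tb$X, noise = noise)
    y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.6, 1, seed = 880 + s)
    el <- backward_eliminate(y, X, tb$w)
    "noise" %in% el$trace$dropped && setequal(el$retained, c("x1", "x2"))
  }, TRUE)
  expect_gte(mean(dropped), 0.8)
  # protection freezes the full model
  noise <- withr::with_seed(81, stats::rnorm(tb$w$n))
  X <- cbind(tb$X, noise = noise)
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.6, 1, seed = 80)
  el2 <- backward_eliminate(y, X, tb$w, protected = c("x1", "x2", "noise"))
  expect_equal(nrow(el2$trace), 0L)
  expect_setequal(el2$retained, c("x1", "x2", "noise"))
  # a single significant unprotected term is retained
  el3 <- backward_eliminate(y, X[, c(1, 2)], tb$w)
  expect_equal(el3$retained, "x1")
})

test_that("neighborhood selection flags the AIC minimum and is deterministic", {
  tb <- sar_testbed(seed = 9)
  y <- gen_sar_response(tb$X, tb$w, c(1, 2, -1), 0.5, 1, seed = 90)
  co <- tb$w$coords
  tab1 <- select_neighborhood(y, tb$X, co, 15)
  expect_equal(nrow(tab1), 1L)
  expect_true(tab1$best)
  # thresholds 11 and 13 induce the same rook neighbor sets -> same AIC
  tab2 <- select_neighborhood(y, tb$X, co, c(11, 13))
  expect_equal(tab2$aic[1], tab2$aic[2], tolerance = 1e-9)
})
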