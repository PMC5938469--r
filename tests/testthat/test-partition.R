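test_that("LMG shares equal the factorial-enumeration oracle (p = 3)", {
  withr::with_seed(17, {
    n <- 60
    X <- matrix(stats::rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    X[, 2] <- X[, 2] + 0.6 * X[, 1] # correlated design
    X[, 3] <- X[, 3] - 0.3 * X[, 1]
    y <- drop(X %*% c(1, 0.5, -0.7)) + stats::rnorm(n)
  })
  res <- lmg_shares(y, X)
  oracle <- lmg_oracle(y, X)
  expect_equal(stats::setNames(res$shares$share, res$shares$term), oracle,
               tolerance = 1e-10)
  expect_equal(sum(res$shares$share), res$r2_full, tolerance = 1e-9)
})

test_that("orthogonal predictors split R2 into squared correlations", {
  withr::with_seed(18, {
    Z <- matrix(stats::rnorm(200 * 2), 200, 2)
    X <- qr.Q(qr(cbind(1, Z)))[, 2:3] # exactly orthogonal, mean zero
    colnames(X) <- c("u", "v")
    y <- drop(X %*% c(2, 1)) + stats::rnorm(200)
  })
  res <- lmg_shares(y, X)
  expect_equal(res$shares$share, c(stats::cor(y, X[, 1])^2,
                                   stats::cor(y, X[, 2])^2), tolerance = 1e-10)
  # single predictor owns the full R2
  res1 <- lmg_shares(y, X[, 1, drop = FALSE])
  expect_equal(res1$shares$share, res1$r2_full, tolerance = 1e-12)
})

test_that("LMG is permutation invariant and respects protected reporting", {
  withr::with_seed(19, {
    X <- matrix(stats::rnorm(80 * 3), 80, 3,
                dimnames = list(NULL, c("effort", "fd", "sfd")))
    y <- drop(X %*% c(1, 1, 0.3)) + stats::rnorm(80)
  })
  a <- lmg_shares(y, X, protected = "effort")
  b <- lmg_shares(y, X[, c("sfd", "effort", "fd")], protected = "effort")
  expect_equal(stats::setNames(a$shares$share, a$shares$term)[c("fd", "sfd")],
               stats::setNames(b$shares$share, b$shares$term)[c("fd", "sfd")],
               tolerance = 1e-10)
  expect_equal(a$total_r2_excluding_protected,
               sum(a$shares$share[a$shares$term != "effort"]), tolerance = 1e-12)
  expect_lt(a$total_r2_excluding_protected, a$r2_full)
  # rank-deficient designs are named
  Xd <- cbind(X, dup = X[, "fd"])
  expect_error(lmg_shares(y, Xd), "rank-deficient")
  expect_error(lmg_shares(y, matrix(stats::rnorm(80 * 11), 80, 11)), "10 predictors")
})

test_that("despatialization removes the spatial error component", {
  co <- grid_coords(12, 12)
  w <- build_weights(co, threshold_km = 15)
  X <- withr::with_seed(21, cbind(1, x1 = stats::rnorm(144)))
  # lambda = 0: adjusted response is exactly y
  y0 <- gen_sar_response(X, w, c(1, 2), 0, 1, seed = 210)
  f0 <- fit_sar_error(y0, X, w, fix_lambda = 0)
  expect_equal(as.numeric(despatialize(f0)), as.numeric(y0), tolerance = 1e-12)
  expect_equal(as.numeric(despatialize(f0, "trend")),
               as.numeric(f0$fitted_trend))
  # lambda = 0.6: whitening shrinks residual variance and kills Moran signal
  y <- gen_sar_response(X, w, c(1, 2), 0.6, 1, seed = 211)
  f <- fit_sar_error(y, X, w)
  raw_resid <- y - f$fitted_trend
  adj_resid <- despatialize(f) - f$fitted_trend
  expect_lt(stats::var(adj_resid), stats::var(raw_resid))
  expect_lt(abs(morans_i(adj_resid, w)$z), 2)
  expect_gt(morans_i(raw_resid, w)$z, 2)
})

test_that("model-type comparison table carries shares, AIC and winner flags", {
  co <- grid_coords(8, 8)
  w <- build_weights(co, threshold_km = 15)
  withr::with_seed(23, {
    X <- cbind(1, fd = stats::rnorm(64), n_hab = stats::rnorm(64))
    y <- gen_sar_response(X, w, c(0, 1.5, 0.2), 0.3, 1, seed = 230)
  })
  fit_fd <- fit_sar_error(y, X[, c(1, 2)], w)
  fit_hb <- fit_sar_error(y, X[, c(1, 3)], w)
  part_fd <- lmg_shares(despatialize(fit_fd), X[, 2, drop = FALSE])
  part_hb <- lmg_shares(despatialize(fit_hb), X[, 3, drop = FALSE])
  cmp <- compare_model_types(list(
    list(response = "y", model_type = "functional_diversity",
         fit = fit_fd, partition = part_fd),
    list(response = "y", model_type = "habitat",
         fit = fit_hb, partition = part_hb)))
  expect_setequal(names(cmp$table),
                  c("response", "model_type", "term", "beta", "z", "r2_pct"))
  expect_setequal(names(cmp$summary),
                  c("response", "model_type", "aic", "total_r2_pct",
                    "winner_aic", "winner_r2"))
  expect_equal(sum(cmp$summary$winner_aic), 1L)
  # identical fits tie on both criteria
  cmp_tie <- compare_model_types(list(
    list(response = "y", model_type = "functional_diversity",
         fit = fit_fd, partition = part_fd),
    list(response = "y", model_type = "habitat",
         fit = fit_fd, partition = part_fd)))
  expect_equal(sum(cmp_tie$summary$winner_aic), 2L)
  expect_equal(sum(cmp_tie$summary$winner_r2), 2L)
  # missing counterpart errors
  expect_error(compare_model_types(list(
    list(response = "y", model_type = "habitat", fit = fit_hb,
         partition = part_hb),
    list(response = "z", model_type = "functional_diversity", fit = fit_fd,
         partition = part_fd))), "lacks one model type")
})
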