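make_test_panel <- function(n = 25, T_ = 6, seed = 1, sigma = 1,
                            rho = 0, theta = c(0, 0),
                            fe_unit_sd = 1, fe_time_sd = 0.5,
                            fe_x_corr = 0) {
  w <- lattice_weights(sqrt(n), sqrt(n))
  cfg <- sdm_dgp_config(n_units = n, T_periods = T_, rho = rho,
                        beta = c(1, -0.5), theta = theta, sigma = sigma,
                        fe_unit_sd = fe_unit_sd, fe_time_sd = fe_time_sd,
                        fe_x_corr = fe_x_corr)
  c(simulate_sdm_panel(w, cfg, seed = seed), list(w = w))
}

test_that("within OLS recovers coefficients in the noiseless limit", {
  d <- make_test_panel(sigma = 1e-10, seed = 3)
  fit <- fit_panel_ols(d$panel, effects = "both")
  expect_equal(unname(fit$beta), c(1, -0.5), tolerance = 1e-8)
})

test_that("a time-invariant covariate is named in the rank error", {
  d <- make_test_panel(seed = 4)
  pan <- d$panel
  pan$X$frozen <- matrix(rep(rnorm(pan$regions$n), length(pan$times)),
                         pan$regions$n)
  pan$k <- 3L
  expect_error(fit_panel_ols(pan, effects = "space"), "frozen")
})

test_that("two-way effects reduce bias relative to pooled OLS", {
  biases <- sapply(1:30, function(s) {
    d <- make_test_panel(seed = 100 + s, fe_x_corr = 0.6,
                         fe_unit_sd = 2)
    pooled <- fit_panel_ols(d$panel, effects = "pooled")
    both <- fit_panel_ols(d$panel, effects = "both")
    c(abs(pooled$beta[["x1"]] - 1), abs(both$beta[["x1"]] - 1))
  })
  expect_lt(mean(biases[2, ]), mean(biases[1, ]))
})

test_that("LM statistics are non-negative and chi-square referenced", {
  d <- make_test_panel(seed = 5, rho = 0.4)
  lm <- lm_spatial_tests(fit_panel_ols(d$panel, "both"), d$w)
  for (t in lm) {
    expect_gte(t$statistic, 0)
    expect_gt(t$p, 0)
    expect_lte(t$p, 1)
  }
  # under a strong lag DGP the lag test dominates
  expect_lt(lm$lm_lag$p, 0.01)
})

test_that("likelihoods nest: SDM >= SAR >= within OLS, SDM >= SEM", {
  for (s in 1:5) {
    d <- make_test_panel(seed = 200 + s, rho = 0.3, theta = c(0.2, 0))
    sdm <- fit_spatial_panel(d$panel, d$w, "SDM", "both")
    sar <- fit_spatial_panel(d$panel, d$w, "SAR", "both")
    sem <- fit_spatial_panel(d$panel, d$w, "SEM", "both")
    ols <- fit_panel_ols(d$panel, "both")
    expect_gte(sdm$loglik, sar$loglik - 1e-6)
    expect_gte(sdm$loglik, sem$loglik - 1e-6)
    expect_gte(sar$loglik, ols$loglik - 1e-6)
  }
})

test_that("concentrated likelihood optimum matches a dense grid search", {
  set.seed(555)
  for (s in 1:20) {
    n_side <- sample(3:5, 1)
    d <- make_test_panel(n = n_side^2, T_ = 5, seed = 300 + s,
                         rho = runif(1, -0.5, 0.7))
    fit <- fit_spatial_panel(d$panel, d$w, "SAR", "both")
    cll <- sar_concentrated_profile(d$panel, d$w)
    grid <- seq(fit$interval[1] + 1e-6, fit$interval[2] - 1e-6,
                by = 1e-3)
    best <- grid[which.max(vapply(grid, cll, 0))]
    expect_lt(abs(best - fit$rho), 1e-3 + 1e-9)
  }
})

test_that("T = 1 pooled SAR matches a brute-force full-likelihood oracle", {
  set.seed(42)
  w <- lattice_weights(5, 5)
  n <- 25
  X <- matrix(rnorm(n * 2), n, 2)
  A_inv <- solve(diag(n) - 0.45 * w$W)
  y <- drop(A_inv %*% (0.5 + X %*% c(1, -0.5) + rnorm(n, sd = 0.5)))
  pan <- panel_data(matrix(y, n, 1),
                    list(x1 = matrix(X[, 1], n, 1),
                         x2 = matrix(X[, 2], n, 1)),
                    w$regions, times = 2020)
  fit <- fit_spatial_panel(pan, w, "SAR", "pooled")
  oracle <- sar_cross_section_brute(y, X, w$W)
  expect_equal(fit$rho, oracle$rho, tolerance = 1e-5)
  expect_equal(unname(fit$beta[c("x1", "x2")]), oracle$beta[2:3],
               tolerance = 1e-5)
})

test_that("parameter recovery sharpens as the panel grows", {
  err <- function(n_side, T_, reps, seed0) {
    e <- sapply(seq_len(reps), function(s) {
      d <- make_test_panel(n = n_side^2, T_ = T_, seed = seed0 + s,
                           rho = 0.4, theta = c(0.3, 0))
      f <- fit_spatial_panel(d$panel, d$w, "SDM", "both")
      (f$rho - 0.4)^2
    })
    sqrt(mean(e))
  }
  small <- err(5, 5, 25, 7000)
  large <- err(10, 10, 25, 8000)
  expect_lt(large, small)
})

test_that("SDM wald and LR reduction tests are coherent", {
  d <- make_test_panel(seed = 31, rho = 0.4, theta = c(0.5, 0.5))
  sdm <- fit_spatial_panel(d$panel, d$w, "SDM", "both")
  sar <- fit_spatial_panel(d$panel, d$w, "SAR", "both")
  wt <- wald_reduction_tests(sdm)
  expect_gte(wt$wald_sar$statistic, 0)
  expect_gte(wt$wald_sem$statistic, 0)
  expect_lt(wt$wald_sar$p, 0.05)     # theta is far from zero here
  lr <- lr_test(sar, sdm, df = 2, name = "LR SDM->SAR")
  expect_lt(lr$p, 0.05)
  # identical fits: LR exactly zero, p = 1
  same <- lr_test(sdm, sdm, df = 2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # reversed nesting errors
  expect_error(lr_test(sdm, sar, df = 2), "nested|lower")
})

test_that("Hausman contrast is zero on identical fits and detects FE", {
  d <- make_test_panel(seed = 32, rho = 0.3, theta = c(0.3, 0),
                       fe_x_corr = 0.6, fe_time_sd = 0)
  fe <- fit_spatial_panel(d$panel, d$w, "SDM", "space")
  re <- fit_spatial_panel(d$panel, d$w, "SDM", "random")
  h <- hausman_test(fe, re)
  expect_gte(h$statistic, 0)
  expect_gt(h$p, 0)
  h0 <- hausman_test(fe, fe)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p, 1)
})

test_that("effects decomposition closed forms hold", {
  d <- make_test_panel(seed = 33, rho = 0.4, theta = c(0.3, 0))
  fit <- fit_spatial_panel(d$panel, d$w, "SDM", "both")

  # rho = 0: direct = beta, indirect = theta exactly
  f0 <- fit
  f0$rho <- 0
  e0 <- decompose_effects(f0, d$w, n_draws = 0)
  tab <- e0$table
  for (j in seq_along(fit$beta)) {
    expect_equal(tab$estimate[tab$covariate == names(fit$beta)[j] &
                                tab$effect == "direct"],
                 unname(fit$beta[j]), tolerance = 1e-12)
    expect_equal(tab$estimate[tab$covariate == names(fit$beta)[j] &
                                tab$effect == "indirect"],
                 unname(fit$theta[j]), tolerance = 1e-12)
  }

  # SAR with rho = 0.5: total = beta / (1 - 0.5) = 2 beta
  sar <- fit_spatial_panel(d$panel, d$w, "SAR", "both")
  sar$rho <- 0.5
  es <- decompose_effects(sar, d$w, n_draws = 0)
  ts <- es$table
  for (j in seq_along(sar$beta)) {
    expect_equal(ts$estimate[ts$covariate == names(sar$beta)[j] &
                               ts$effect == "total"],
                 unname(2 * sar$beta[j]), tolerance = 1e-10)
  }

  # total = direct + indirect identically, with simulated inference on
  ef <- decompose_effects(fit, d$w, n_draws = 200, seed = 9)
  tt <- ef$table
  for (cv in unique(tt$covariate)) {
    expect_equal(tt$estimate[tt$covariate == cv & tt$effect == "total"],
                 tt$estimate[tt$covariate == cv & tt$effect == "direct"] +
                   tt$estimate[tt$covariate == cv &
                                 tt$effect == "indirect"],
                 tolerance = 1e-12)
  }
  expect_true(all(is.finite(tt$sd)))
  expect_error(decompose_effects(fit, d$w, n_draws = 10), "seed")
})

test_that("VIF anchors: orthogonal columns, R2 = 0.9, exact collinearity", {
  # exactly orthogonal, centred columns (orthogonal to the intercept too)
  set.seed(60)
  X <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, -1]
  colnames(X) <- paste0("x", 1:3)
  v <- vif(X)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-8)

  # construct x2 so the auxiliary R2 of x1 on x2 is exactly 0.9
  set.seed(6)
  z1 <- scale(rnorm(500)); z2 <- scale(rnorm(500))
  z2 <- scale(z2 - z1 * drop(crossprod(z1, z2) / crossprod(z1)))
  x1 <- z1
  x2 <- sqrt(0.9) * z1 + sqrt(0.1) * z2
  v2 <- vif(cbind(a = x1, b = x2))
  expect_equal(v2$vif[1], 10, tolerance = 1e-8)

  # exact collinearity flagged on all members
  x3 <- x1 + x2
  v3 <- vif(cbind(a = x1, b = x2, c = x3))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(all(v3$flag == "exact collinearity"))
})

test_that("unbalanced or duplicated long tables are rejected", {
  df <- expand.grid(unit_id = c("A", "B", "C"), year = 2001:2004)
  df$y <- rnorm(12); df$x1 <- rnorm(12)
  p <- panel_from_long(df, outcome = "y", covariates = "x1")
  expect_s3_class(p, "panel_data")
  expect_error(panel_from_long(df[-1, ], outcome = "y",
                               covariates = "x1"), "unbalanced")
  df2 <- rbind(df, df[1, ])
  expect_error(panel_from_long(df2, outcome = "y", covariates = "x1"),
               "duplicated")
})
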