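cascade_fixture <- function(seed = 1, rho = 0.4, theta = c(0.5, 0.5),
                            fe_x_corr = 0.5, fe_time_sd = 0.5) {
  w <- lattice_weights(7, 7)
  cfg <- sdm_dgp_config(n_units = 49, T_periods = 8, rho = rho,
                        beta = c(1, -0.5), theta = theta,
                        fe_x_corr = fe_x_corr, fe_time_sd = fe_time_sd)
  list(w = w, panel = simulate_sdm_panel(w, cfg, seed = seed)$panel)
}

test_that("cascade trace equals stage-by-stage manual invocation", {
  d <- cascade_fixture(seed = 5)
  tr <- run_selection_cascade(d$panel, d$w, alpha = 0.1)

  ols <- fit_panel_ols(d$panel, "both")
  lm <- lm_spatial_tests(ols, d$w, alpha = 0.1)
  sdm <- fit_spatial_panel(d$panel, d$w, "SDM", "both")
  wd <- wald_reduction_tests(sdm, alpha = 0.1)
  sar <- fit_spatial_panel(d$panel, d$w, "SAR", "both")
  sem <- fit_spatial_panel(d$panel, d$w, "SEM", "both")
  lr_sar <- lr_test(sar, sdm, df = 2, name = "LR SDM->SAR")
  lr_sem <- lr_test(sem, sdm, df = 2, name = "LR SDM->SEM")
  fe <- fit_spatial_panel(d$panel, d$w, "SDM", "space")
  re <- fit_spatial_panel(d$panel, d$w, "SDM", "random")
  hm <- hausman_test(fe, re, alpha = 0.1)

  manual <- c(lm$lm_lag$statistic, lm$lm_error$statistic,
              lm$rlm_lag$statistic, lm$rlm_error$statistic,
              wd$wald_sar$statistic, wd$wald_sem$statistic,
              lr_sar$statistic, lr_sem$statistic, hm$statistic)
  expect_equal(tr$steps$statistic[1:9], manual, tolerance = 1e-10)
  expect_equal(tr$fit$rho, sdm$rho)
  expect_equal(tr$fit$beta, sdm$beta)
  expect_true(all(tr$steps$p >= 0 & tr$steps$p <= 1))
})

test_that("no spatial effect sends the cascade to within OLS", {
  w <- lattice_weights(7, 7)
  cfg <- sdm_dgp_config(n_units = 49, T_periods = 8, rho = 0,
                        beta = c(1, -0.5), theta = c(0, 0))
  hits <- sapply(1:10, function(s) {
    pan <- simulate_sdm_panel(w, cfg, seed = 40 + s)$panel
    tr <- run_selection_cascade(pan, w, alpha = 0.1)
    tr$model == "OLS"
  })
  expect_gt(mean(hits), 0.5)
  # and the OLS fallback trace stops after the LM battery
  pan <- simulate_sdm_panel(w, cfg, seed = 41)$panel
  tr <- run_selection_cascade(pan, w, alpha = 1e-12)
  expect_equal(tr$model, "OLS")
  expect_equal(nrow(tr$steps), 4)
  expect_true(all(tr$steps$decision == "keep H0"))
})

test_that("degenerate alpha keeps the trace well-formed", {
  d <- cascade_fixture(seed = 6)
  tr <- run_selection_cascade(d$panel, d$w, alpha = 1e-12)
  expect_s3_class(tr, "selection_trace")
  expect_true(tr$model %in% c("OLS", "SAR", "SEM", "SDM"))
  expect_true(all(c("test", "statistic", "p", "decision") %in%
                    names(tr$steps)))
})

test_that("run_study writes schema-stable tables, deterministically", {
  w <- lattice_weights(5, 5)
  cfg <- sdm_dgp_config(n_units = 25, T_periods = 5, rho = 0.4,
                        beta = c(1, -0.5), theta = c(0.3, 0),
                        fe_x_corr = 0.5)
  pan <- simulate_sdm_panel(w, cfg, seed = 77)$panel
  monthly <- simulate_monthly_series(2015:2019, peak_month = 11,
                                     kappa = 2, seed = 78)
  out1 <- tempfile("study1"); out2 <- tempfile("study2")
  config <- list(panel = pan, weights = w, monthly = monthly,
                 out_dir = out1, seed = 42, n_perm = 199, n_draws = 200)
  res <- run_study(config)

  files <- c("global_moran_by_year.csv", "lisa_clusters_by_year.csv",
             "model_coefficients.csv", "test_battery.csv", "vif.csv",
             "concentration_by_year.csv", "run_log.json")
  for (f in files) expect_true(file.exists(file.path(out1, f)))
  expect_equal(nrow(res$moran), 5)
  expect_named(res$moran, c("year", "I", "expected_I", "z",
                            "p_analytic", "p_perm"))
  expect_equal(nrow(res$vif), 2)
  expect_equal(nrow(res$concentration), 5)

  config2 <- config; config2$out_dir <- out2
  run_study(config2)
  for (f in setdiff(files, "run_log.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # missing config keys fail before any computation
  expect_error(run_study(list(panel = pan)), "missing")
})

test_that("long-CSV and GAL inputs drive the same study pipeline", {
  w <- lattice_weights(4, 4)
  cfg <- sdm_dgp_config(n_units = 16, T_periods = 4, rho = 0.3,
                        beta = c(1, -0.5), theta = c(0.2, 0))
  sim <- simulate_sdm_panel(w, cfg, seed = 9)
  long <- data.frame(
    unit_id = rep(region_ids(w), 4),
    year = rep(seq_len(4), each = 16),
    y = as.vector(sim$panel$y),
    x1 = as.vector(sim$panel$X$x1),
    x2 = as.vector(sim$panel$X$x2)
  )
  csv <- tempfile(fileext = ".csv")
  write.csv(long, csv, row.names = FALSE)
  gal <- tempfile(fileext = ".gal")
  write_gal(w, gal)
  out <- tempfile("study3")
  res <- run_study(list(panel = csv, weights = gal, out_dir = out,
                        seed = 7, outcome = "y",
                        covariates = c("x1", "x2"), n_perm = 99,
                        n_draws = 100))
  expect_equal(nrow(res$moran), 4)
  expect_true(file.exists(file.path(out, "run_log.json")))
})
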