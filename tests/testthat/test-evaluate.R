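test_that("NRMSE is the RMS of per-observation relative errors, in percent", {
  expect_identical(nrmse(40, 40), 0)
  expect_equal(nrmse(42, 40), 5, tolerance = 1e-9)
  expect_equal(nrmse(c(42, 38), c(40, 40)), 5, tolerance = 1e-12)
  # 5.6% at a reference of 40 breaths/min corresponds to 2.24 breaths/min RMS
  expect_equal(nrmse(40 + 2.24, 40), 5.6, tolerance = 1e-9)
  expect_error(nrmse(numeric(0), numeric(0)), "non-empty")
  expect_error(nrmse(40, 0), "positive")
  expect_error(nrmse(c(40, 40), 40), "equal length")
})

test_that("efficiency statistics penalize failures with the full duration", {
  mk <- function(e, done) list(efficiency = e, completed = done)
  all_done <- lapply(c(6, 8, 10), mk, done = TRUE)
  s <- efficiency_stats(all_done)
  expect_equal(s$e_median, 8)
  expect_equal(s$e_mean, 8)
  expect_equal(s$cr, 100)
  expect_equal(s$n_fail, 0)

  with_fail <- c(lapply(c(6, 8), mk, done = TRUE), list(mk(60, FALSE)))
  s2 <- efficiency_stats(with_fail)
  expect_equal(s2$e_mean, mean(c(6, 8, 60)))
  expect_equal(s2$cr, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(s2$n_fail, 1)

  none <- replicate(5, mk(60, FALSE), simplify = FALSE)
  s3 <- efficiency_stats(none)
  expect_equal(s3$cr, 0)
  expect_equal(s3$e_mean, 60)
  expect_equal(s3$e_p95, 60)

  # with no failures the statistics are the ordinary median/mean/percentile
  e <- c(4, 5, 7, 9, 12, 20)
  s4 <- efficiency_stats(lapply(e, mk, done = TRUE))
  expect_equal(s4$e_median, median(e))
  expect_equal(s4$e_p95, unname(quantile(e, 0.95, type = 7)))
})

test_that("Bland-Altman reports bias and 2-SD limits of agreement", {
  ba0 <- bland_altman(c(40, 30, 20), c(40, 30, 20))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)

  ba <- bland_altman(c(41, 39), c(40, 40))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2), tolerance = 1e-9)

  ba2 <- bland_altman(c(42, 42, 38, 38), c(40, 40, 40, 40))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd, sqrt(16 / 3), tolerance = 1e-9)
  expect_equal(ba2$loa_high, 2 * sqrt(16 / 3), tolerance = 1e-9) # +/- 4.62
  expect_equal(ba2$loa_low, -ba2$loa_high)
  expect_lte(ba2$loa_low, ba2$bias)

  expect_error(bland_altman(40, 40), "at least 2")
})

test_that("noise-free logs give a perfect grid", {
  logs <- lapply(1:6, function(i) {
    simulate_taps(40, breath_cv = 0, tap_jitter_sd = 0, p_missed = 0,
                  p_extra = 0, seed = i)
  })
  g <- replay_grid(logs, z_values = 2:4, th_c_values = c(5, 13))
  expect_true(all(g$nrmse == 0))
  expect_true(all(g$cr == 100))
  expect_equal(attr(g, "reference_nrmse"), 0)
  # disabled column present once per z
  expect_equal(sum(is.na(g$th_c)), 3)
  expect_equal(nrow(g), 3 * 2 + 3)
})

test_that("grid agrees with per-log streaming estimation cell by cell", {
  logs <- simulate_study(n_subjects = 2, seed = 15)
  g <- replay_grid(logs, z_values = c(3, 5), th_c_values = c(8, 20))
  for (r in seq_len(nrow(g))) {
    th <- if (is.na(g$th_c[r])) Inf else g$th_c[r]
    ref <- evaluate_config(logs, z = g$z[r], th_c = th)
    for (col in c("nrmse", "e_median", "e_mean", "e_p95", "cr", "n_fail")) {
      expect_equal(g[[col]][r], ref[[col]], tolerance = 1e-12)
    }
  }
})

test_that("mean efficiency never increases as the threshold loosens", {
  logs <- simulate_study(n_subjects = 4, seed = 21)
  g <- replay_grid(logs, z_values = c(2, 4, 8), th_c_values = 2:30)
  for (z in unique(g$z)) {
    gz <- g[g$z == z & !is.na(g$th_c), ]
    gz <- gz[order(gz$th_c), ]
    expect_true(all(diff(gz$e_mean) <= 1e-9))
    expect_true(all(diff(gz$cr) >= -1e-9))
  }
})

test_that("cells where nothing completes are flagged, not invented", {
  # alternating 1 s / 2 s intervals never reach consistency 2% at z = 2
  tt <- cumsum(c(0, rep(c(1, 2), 10)))
  g <- replay_grid(list(tap_log(tt, rr_ref = 40)), z_values = 2,
                   th_c_values = 2, include_disabled = FALSE)
  expect_equal(g$cr, 0)
  expect_true(is.na(g$nrmse))
  expect_equal(g$e_mean, 60)
})

test_that("regression summary recovers exact linear surfaces", {
  cells <- expand.grid(z = 2:6, th_c = c(5, 10, 15, 20))
  g <- data.frame(cells, n = 10, n_fail = 0, cr = 100,
                  nrmse = 10 - cells$z,
                  e_median = 30 - cells$th_c / 2 + cells$z,
                  e_mean = 10, e_p95 = 20)
  class(g) <- c("rr_grid", "data.frame")
  # summary.lm warns about an exactly perfect fit; that is the point here
  fit <- suppressWarnings(regression_summary(g))
  expect_equal(fit$nrmse_r2, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit$nrmse_fit)["z"]), -1, tolerance = 1e-9)
  expect_equal(unname(coef(fit$nrmse_fit)["th_c"]), 0, tolerance = 1e-9)
  expect_equal(unname(coef(fit$e_median_fit)["th_c"]), -0.5, tolerance = 1e-9)

  g2 <- g
  g2$nrmse <- 7
  fit2 <- suppressWarnings(regression_summary(g2))
  expect_equal(unname(coef(fit2$nrmse_fit)["z"]), 0, tolerance = 1e-9)
  expect_equal(unname(coef(fit2$nrmse_fit)["th_c"]), 0, tolerance = 1e-9)

  expect_error(regression_summary(g[g$z == 2, ]), "distinct")
})

test_that("looser thresholds speed up measurement in the simulated study", {
  logs <- simulate_study(n_subjects = 5, seed = 33)
  g <- replay_grid(logs, z_values = c(3, 4, 5), th_c_values = seq(4, 28, by = 4))
  fit <- regression_summary(g)
  expect_lt(unname(coef(fit$e_median_fit)["th_c"]), 0)
})
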