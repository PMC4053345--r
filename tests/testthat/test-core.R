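test_that("interval extraction differences strictly increasing timestamps", {
  expect_equal(intervals_from_taps(c(0, 1.5, 3.0, 4.5)), c(1.5, 1.5, 1.5))
  expect_equal(intervals_from_taps(c(0, 1.0, 2.2, 3.6, 5.6)), c(1.0, 1.2, 1.4, 2.0))
  expect_error(intervals_from_taps(numeric(0)), "at least 2")
  expect_error(intervals_from_taps(0.0), "at least 2")
  expect_error(intervals_from_taps(c(0, 1, 1)), "strictly increasing")
  expect_error(intervals_from_taps(c(0, 2, 1)), "strictly increasing")
})

test_that("median interval follows the order-statistic convention", {
  expect_equal(median_interval(c(1.5, 1.5, 1.5)), 1.5)
  expect_equal(median_interval(c(1.0, 1.2, 1.4, 2.0)), 1.3, tolerance = 1e-12)
  expect_equal(median_interval(c(2.0, 1.0, 1.2)), 1.2)
  expect_error(median_interval(numeric(0)), "at least one")
  expect_error(median_interval(c(1, -1)), "positive")
})

test_that("consistency is the maximum percentage deviation from the median", {
  expect_identical(consistency(c(1.5, 1.5, 1.5)), 0)
  expect_equal(consistency(c(1.0, 1.2, 1.4, 2.0)), 100 * 0.7 / 1.3, tolerance = 1e-12)
  expect_equal(consistency(c(1.0, 1.2, 1.4, 2.0)), 53.84615384615385, tolerance = 1e-9)
  expect_equal(consistency(c(1.0, 1.1, 1.0)), 10, tolerance = 1e-12)
  expect_error(consistency(1.5), "at least 2")
})

test_that("rate conversion divides 60 s by the median interval", {
  expect_equal(rr_from_median(1.5), 40)
  expect_equal(rr_from_median(1.0), 60)
  expect_equal(rr_from_median(1.3), 46.153846153846153, tolerance = 1e-9)
  expect_error(rr_from_median(0), "positive")
  expect_error(rr_from_median(-1.5), "positive")
})

test_that("set evaluation accepts at and below the threshold, rejects above", {
  expect_true(evaluate_set(c(1.5, 1.5, 1.5, 1.5), 13)$accepted)
  expect_false(evaluate_set(c(1.0, 1.2, 1.4, 2.0), 13)$accepted)
  # exactly-representable boundary: max deviation 0.25 on median 1.0 -> C = 25
  bnd <- evaluate_set(c(1.0, 1.25, 1.0, 1.0), 25)
  expect_equal(bnd$set$consistency, 25)
  expect_true(bnd$accepted)
  expect_false(evaluate_set(c(1.0, 1.25, 1.0, 1.0), 24.999)$accepted)
  # the returned set carries the statistics of its intervals
  res <- evaluate_set(c(1.0, 1.2, 1.4, 2.0), 13)
  expect_s3_class(res$set, "interval_set")
  expect_equal(res$set$median_interval, 1.3)
})

test_that("streaming estimator accepts the first consistent window", {
  e <- estimate_rr(c(0, 1.5, 3.0, 4.5, 6.0), z = 4, th_c = 13)
  expect_true(e$completed)
  expect_equal(e$rr, 40)
  expect_equal(e$efficiency, 6.0)
  expect_equal(e$taps_used, 5L)
  expect_equal(e$accepted_set$consistency, 0)

  # early windows contain 3 s and 4 s outlier intervals; the first clean
  # window of four 1 s intervals ends at t = 13
  e2 <- estimate_rr(c(0, 1.0, 4.0, 5.0, 9.0, 10, 11, 12, 13), z = 4, th_c = 13)
  expect_true(e2$completed)
  expect_equal(e2$rr, 60)
  expect_equal(e2$efficiency, 13.0)
  expect_equal(e2$taps_used, 9L)
})

test_that("disabled threshold accepts the first full set of z+1 taps", {
  tt <- constant_taps(10)
  for (z in c(2, 4, 7)) {
    e <- estimate_rr(tt, z = z, th_c = "off")
    expect_true(e$completed)
    expect_equal(e$taps_used, z + 1L)
  }
  expect_equal(estimate_rr(tt, z = 4, th_c = Inf)$taps_used,
               estimate_rr(tt, z = 4, th_c = NA)$taps_used)
})

test_that("too few taps yields an incomplete estimate, not an error", {
  e <- estimate_rr(c(0, 1.5, 3.0), z = 4, th_c = "off")
  expect_false(e$completed)
  expect_true(is.na(e$rr))
  expect_equal(e$efficiency, 60)
  e0 <- estimate_rr(numeric(0), z = 4, th_c = 13)
  expect_false(e0$completed)
})

test_that("out-of-range rates are treated as not valid and tapping continues", {
  # 0.3 s spacing implies 200 breaths/min, above the reportable maximum
  fast <- constant_taps(12, spacing = 0.3)
  e <- estimate_rr(fast, z = 2, th_c = "off")
  expect_false(e$completed)
  # slows down into range later: early out-of-range windows are skipped
  tt <- c(0, 0.3, 0.6, 0.9, 0.9 + cumsum(rep(1.5, 4)))
  e2 <- estimate_rr(tt, z = 2, th_c = 13)
  expect_true(e2$completed)
  expect_equal(e2$rr, 40)
})

test_that("the measurement cap is counted from the first tap", {
  tt <- c(0, 30, 61, 62, 63, 64, 65)
  e <- estimate_rr(tt, z = 2, th_c = "off")
  expect_false(e$completed) # all complete windows end beyond 60 s after the first tap
  expect_equal(e$efficiency, 60)
  # the same taps shifted by +100 s behave identically
  e_shift <- estimate_rr(tt + 100, z = 2, th_c = "off")
  expect_equal(e_shift$completed, e$completed)
  # a window ending exactly at the cap still reports
  e_edge <- estimate_rr(c(0, 20, 40, 60), z = 3, th_c = "off", rr_min = 2)
  expect_true(e_edge$completed)
  expect_equal(e_edge$efficiency, 60)
})

test_that("estimator validates its inputs", {
  expect_error(estimate_rr(c(0, 1, 0.5), z = 2, th_c = 13), "strictly increasing")
  expect_error(estimate_rr(c(0, 1, 2), z = 1, th_c = 13), "z must be")
  expect_error(estimate_rr(c(0, 1, 2), z = 2, th_c = -5), "positive")
  expect_error(estimate_rr(c(0, 1, 2), z = 2, th_c = 13, rr_min = 50, rr_max = 40),
               "rr_min")
})

test_that("tap_log validates and carries its fields", {
  l <- tap_log(c(0, 1.5, 3), rr_ref = 40, subject_id = "a", video_id = "b")
  expect_equal(l$rr_ref, 40)
  expect_error(tap_log(c(0, 1, 1), rr_ref = 40), "strictly increasing")
  expect_error(tap_log(c(0, 1, 2), rr_ref = 0), "positive")
  e <- estimate_rr(l, z = 2, th_c = 13)
  expect_equal(e$rr_ref, 40)
  expect_equal(e$subject_id, "a")
})
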