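test_that("an exact power law is fitted without error", {
  cv <- fit_calibration(make_power_law_calibration())
  expect_equal(unname(coef(cv)[["slope"]]), -1, tolerance = 1e-12)
  expect_equal(unname(coef(cv)[["intercept"]]), 0, tolerance = 1e-12)
  expect_equal(cv$residual_sd, 0, tolerance = 1e-9)
})

test_that("the two-anchor fit recovers the closed-form slope", {
  anchors <- data.frame(keap1_level_pct = c(100, 100, 26, 26),
                        mrna_rel = c(1, 1, 4, 4))
  cv <- fit_calibration(anchors)
  slope_oracle <- log(4) / log(26 / 100)  # two-point closed form
  expect_equal(unname(coef(cv)[["slope"]]), slope_oracle, tolerance = 1e-9)
  expect_equal(round(slope_oracle, 4), -1.0291)
})

test_that("non-inverse relationships and insufficient data are rejected", {
  up <- data.frame(keap1_level_pct = c(100, 40, 19, 5),
                   mrna_rel = c(1, 0.5, 0.25, 0.1))
  expect_error(fit_calibration(up), "inverse")
  one_level <- data.frame(keap1_level_pct = c(50, 50), mrna_rel = c(1, 2))
  expect_error(fit_calibration(one_level), "distinct")
  neg <- data.frame(keap1_level_pct = c(100, -5), mrna_rel = c(1, 2))
  expect_error(fit_calibration(neg), "positive")
})

test_that("forward prediction evaluates the fitted power law", {
  cv <- fit_calibration(make_power_law_calibration())
  expect_equal(predict_mrna(cv, 100), 1.0, tolerance = 1e-9)
  expect_equal(predict_mrna(cv, 25), 4.0, tolerance = 1e-9)
  anchors <- data.frame(keap1_level_pct = c(100, 26), mrna_rel = c(1, 4))
  cv2 <- fit_calibration(anchors)
  expect_equal(predict_mrna(cv2, 62),
               exp(log(4) / log(0.26) * log(0.62)), tolerance = 1e-9)
  expect_equal(predict_mrna(cv2, 62), 1.635, tolerance = 1e-3)
  expect_error(predict_mrna(cv, -3), "positive")
})

test_that("inversion is exact, monotone, and clips above baseline", {
  cv <- fit_calibration(make_power_law_calibration())
  expect_equal(invert_activity(cv, 4.0), 25.0, tolerance = 1e-9)
  ## round-trip identity across the dosage range
  for (x in seq(5, 100, by = 5)) {
    expect_equal(invert_activity(cv, predict_mrna(cv, x)), x,
                 tolerance = 1e-9)
  }
  ## strictly monotone decreasing in the observation
  ms <- c(0.5, 1, 1.5, 2, 4, 8)
  inv <- suppressWarnings(invert_activity(cv, ms))
  expect_true(all(diff(inv) < 1e-12))
  expect_warning(invert_activity(cv, 0.5), "clipped")
  expect_equal(suppressWarnings(invert_activity(cv, 0.5)), 100)
  expect_error(invert_activity(cv, 0), "positive")
})

test_that("anchored fit inverts the observed heterozygote induction into the reported interval", {
  anchors <- data.frame(keap1_level_pct = c(100, 100, 26, 26),
                        mrna_rel = c(1, 1, 4, 4))
  cv <- fit_calibration(anchors)
  act <- invert_activity(cv, 1.5)
  expect_equal(act, 100 * 1.5^(log(0.26) / log(4)), tolerance = 1e-9)
  expect_gt(act, 49)
  expect_lt(act, 75)
})

test_that("bootstrap activity estimates are seeded, degenerate-safe and clipped", {
  calib <- make_power_law_calibration(n_rep = 3)
  ## zero noise and identical replicates: the interval collapses
  est <- estimate_activity_ci(calib, c(4, 4, 4), n_boot = 200, seed = 7)
  expect_equal(est$activity_point, 0.25, tolerance = 1e-9)
  expect_equal(est$ci_low, est$activity_point)
  expect_equal(est$ci_high, est$activity_point)

  ## identical seeds give identical estimates; the global RNG is untouched
  tr <- ground_truth(seed = 11)
  noisy <- generate_calibration_dataset(tr)
  obs <- c(3.4, 4.2, 3.9, 4.4, 3.6)
  set.seed(123); before <- rnorm(1)
  a <- estimate_activity_ci(noisy, obs, n_boot = 500, seed = 5)
  b <- estimate_activity_ci(noisy, obs, n_boot = 500, seed = 5)
  expect_identical(a, b)
  set.seed(123); expect_identical(rnorm(1), before)

  c2 <- estimate_activity_ci(noisy, obs, n_boot = 500, seed = 6)
  expect_false(identical(a$ci_low, c2$ci_low))

  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  expect_error(estimate_activity_ci(calib, c(4, 4), n_boot = 50), "n_boot")
  expect_error(estimate_activity_ci(calib, 4), "replicates")
})

test_that("bootstrap CI width shrinks as replicate count grows", {
  tr <- ground_truth(seed = 3)
  calib <- generate_calibration_dataset(tr)
  set.seed(99)
  ## average over observation draws so the comparison reflects the expected
  ## width, not the replicate scatter of one draw
  widths <- vapply(c(3, 5, 20, 100), function(m) {
    mean(vapply(1:20, function(r) {
      obs <- 4 * exp(rnorm(m, 0, 0.1))
      e <- estimate_activity_ci(calib, obs, n_boot = 500, seed = r)
      e$ci_high - e$ci_low
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the fit is scale-equivariant and inversion scale-invariant", {
  tr <- ground_truth(seed = 5)
  calib <- generate_calibration_dataset(tr)
  cv <- fit_calibration(calib)
  scaled <- calib
  scaled$mrna_rel <- scaled$mrna_rel * 2.5
  cv2 <- fit_calibration(scaled)
  expect_equal(coef(cv2)[["slope"]], coef(cv)[["slope"]], tolerance = 1e-9)
  expect_equal(coef(cv2)[["intercept"]], coef(cv)[["intercept"]] + log(2.5),
               tolerance = 1e-9)
  expect_equal(invert_activity(cv2, 1.5 * 2.5), invert_activity(cv, 1.5),
               tolerance = 1e-9)
})
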