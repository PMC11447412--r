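test_that("random pairing yields Hardy-Weinberg dimer fractions", {
  pop <- dimer_composition(0.5)
  expect_equal(c(pop$f_wt_homo, pop$f_het, pop$f_mut_homo),
               c(0.25, 0.50, 0.25))
  pop <- dimer_composition(1.0)
  expect_equal(c(pop$f_wt_homo, pop$f_het, pop$f_mut_homo), c(1, 0, 0))
  pop <- dimer_composition(0.3)
  expect_equal(c(pop$f_wt_homo, pop$f_het, pop$f_mut_homo),
               c(0.09, 0.42, 0.49))
  expect_error(dimer_composition(1.2), "\\[0, 1\\]")
  expect_error(dimer_composition(-0.1), "\\[0, 1\\]")
})

test_that("dimer composition matches exhaustive pair enumeration and sums to 1", {
  for (m in c(4L, 7L, 10L)) {
    for (k in 0:m) {
      pop <- dimer_composition(k / m)
      got <- c(pop$f_wt_homo, pop$f_het, pop$f_mut_homo)
      expect_equal(got, enumerate_dimer_composition(k, m), tolerance = 1e-12)
      expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  }
})

test_that("inactivated fraction is the complement of residual WT activity", {
  expect_equal(infer_homodimer_inactivation(0.26), 0.74)
  expect_equal(infer_homodimer_inactivation(1.0), 0.0)
  expect_equal(infer_homodimer_inactivation(0.5), 0.5)
  expect_error(infer_homodimer_inactivation(1.3), "\\[0, 1\\]")
})

test_that("heterodimer inactivated fraction follows hypothesis and mode", {
  expect_equal(
    heterodimer_inactivated_fraction(inactivation_setting(0.74, "monomer")),
    0.37)
  expect_equal(
    heterodimer_inactivated_fraction(inactivation_setting(0.74, "dimer")),
    0)
  expect_equal(
    heterodimer_inactivated_fraction(
      inactivation_setting(0.74, "dimer", "binomial")), 0)
  ## independent bisection oracle for the per-monomer back-solve
  p_oracle <- uniroot(function(p) 1 - (1 - p)^2 - 0.74, c(0, 1),
                      tol = 1e-12)$root
  expect_equal(
    heterodimer_inactivated_fraction(
      inactivation_setting(0.74, "monomer", "binomial")),
    p_oracle, tolerance = 1e-9)
  expect_equal(round(p_oracle, 6), 0.490098)
})

test_that("predicted total activity reproduces the per-class arithmetic", {
  pop <- dimer_composition(0.5)
  mono <- predict_total_activity(pop, inactivation_setting(0.74, "monomer"))
  expect_equal(mono$total_activity, 0.63)
  expect_equal(mono$contrib_mut_homo, 0.25)
  expect_equal(mono$contrib_wt_homo, 0.065)
  expect_equal(mono$contrib_het, 0.315)
  expect_equal(mono$total_activity,
               mono$contrib_mut_homo + mono$contrib_wt_homo + mono$contrib_het,
               tolerance = 1e-12)

  dim <- predict_total_activity(pop, inactivation_setting(0.74, "dimer"))
  expect_equal(dim$total_activity, 0.815)
  expect_equal(dim$contrib_het, 0.50)

  ## no stress: everything stays active, under either hypothesis
  for (h in c("monomer", "dimer")) {
    expect_equal(
      predict_total_activity(dimer_composition(0.3),
                             inactivation_setting(0, h))$total_activity, 1)
  }

  binom <- predict_total_activity(
    pop, inactivation_setting(0.74, "monomer", "binomial"))
  expect_equal(binom$total_activity, 0.25 + 0.065 + 0.5 * sqrt(0.26),
               tolerance = 1e-12)
  set.seed(42)
  mc <- mc_total_activity(0.74, "monomer", "binomial", n = 2e5)
  expect_lt(abs(binom$total_activity - mc[["est"]]), 3 * mc[["se"]])
})

test_that("hypothesis predictions are ordered and monotone in stress", {
  f_grid <- seq(0.05, 1, by = 0.05)
  for (mode in c("paper_linear", "binomial")) {
    for (w in c(0.2, 0.5, 0.8)) {
      pop <- dimer_composition(w)
      mono <- vapply(f_grid, function(f) predict_total_activity(
        pop, inactivation_setting(f, "monomer", mode))$total_activity,
        numeric(1))
      dimr <- vapply(f_grid, function(f) predict_total_activity(
        pop, inactivation_setting(f, "dimer", mode))$total_activity,
        numeric(1))
      ## one-hit kill always predicts less activity when heterodimers exist
      expect_true(all(mono < dimr))
      ## more stress never predicts more activity
      expect_true(all(diff(mono) <= 1e-12))
      expect_true(all(diff(dimr) <= 1e-12))
    }
  }
  ## equality when no heterodimers exist
  pop <- dimer_composition(1)
  expect_equal(
    predict_total_activity(pop, inactivation_setting(0.6, "monomer"))$total_activity,
    predict_total_activity(pop, inactivation_setting(0.6, "dimer"))$total_activity)
})

test_that("binomial heterodimer rule never predicts more activity than the linear rule", {
  pop <- dimer_composition(0.5)
  for (f in seq(0, 1, by = 0.05)) {
    lin <- predict_total_activity(
      pop, inactivation_setting(f, "monomer", "paper_linear"))$total_activity
    bin <- predict_total_activity(
      pop, inactivation_setting(f, "monomer", "binomial"))$total_activity
    expect_lte(bin, lin + 1e-12)
    if (f == 0) expect_equal(bin, lin)
  }
})

test_that("hypothesis evaluation selects by CI membership", {
  pop <- dimer_composition(0.5)
  v <- evaluate_hypotheses(pop, 0.74, activity_estimate(0.62, 0.49, 0.75))
  expect_equal(v$prediction_monomer, 0.63)
  expect_equal(v$prediction_dimer, 0.815)
  expect_identical(v$selected, "monomer")
  expect_true(v$within_ci[["monomer"]])
  expect_false(v$within_ci[["dimer"]])

  v <- evaluate_hypotheses(pop, 0.74, activity_estimate(0.70, 0.55, 0.90))
  expect_identical(v$selected, "both")
  v <- evaluate_hypotheses(pop, 0.74, activity_estimate(0.30, 0.25, 0.35))
  expect_identical(v$selected, "neither")

  bad <- list(activity_point = 0.6, ci_low = 0.7, ci_high = 0.5)
  expect_error(evaluate_hypotheses(pop, 0.74, bad), "degenerate")
  expect_error(evaluate_hypotheses(pop, 0.74,
                                   list(activity_point = 0.6, ci_low = NA,
                                        ci_high = 0.8)),
               "finite")
})
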