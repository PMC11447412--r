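test_that("HGVS-style protein changes parse in 1- and 3-letter notation", {
  v <- parse_protein_variant("Cys622Ser")
  expect_equal(v$position, 622L)
  expect_identical(c(v$ref_aa, v$alt_aa), c("C", "S"))
  expect_identical(unclass(parse_protein_variant("p.C622S"))[1:3],
                   unclass(v)[1:3])
  expect_identical(format(parse_protein_variant("His225Tyr")), "H225Y")
  expect_error(parse_protein_variant("Cys622Cys"), "synonymous")
  expect_error(parse_protein_variant("Xyz100Ser"), "unknown amino-acid")
  expect_error(parse_protein_variant("not a variant"), "cannot parse")
})

test_that("variants classify by sensor-map position lookup", {
  cl <- classify_variant(keap_variant(622, "C", "S"))
  expect_identical(cl$category, "oxidative_sensor_cys")
  expect_true(cl$destroys_thiol)

  cl <- classify_variant(keap_variant(225, "H", "Y"))
  expect_identical(cl$category, "oxidative_neighbor_basic")
  expect_true(cl$destroys_basicity)
  expect_false(cl$destroys_thiol)

  cl <- classify_variant(keap_variant(614, "R", "K"))
  expect_false(cl$destroys_basicity)  # lysine keeps the basicity

  expect_identical(classify_variant(keap_variant(151, "C", "S"))$category,
                   "electrophile_sensor_cys")
  expect_identical(classify_variant(keap_variant(100, "A", "V"))$category,
                   "non_sensor")

  ## annotation drift: non-Cys reference at a sensor position
  expect_warning(
    cl <- classify_variant(keap_variant(226, "A", "V")),
    "disagrees")
  expect_identical(cl$category, "non_sensor")
})

test_that("classification depends on position and residues only", {
  a <- classify_variant(keap_variant(613, "C", "Y"))
  b <- classify_variant(keap_variant(613, "C", "Y",
                                     allele_freq_panels = c(p = 1e-5)))
  expect_identical(a$category, b$category)
})

test_that("the fail-safe needs two intact parts", {
  fs <- failsafe_oxidative(c(226, 613))
  expect_identical(fs$intact_parts, "P3")
  expect_length(fs$viable_pairs, 0)
  expect_false(fs$functional)

  fs <- failsafe_oxidative(integer())
  expect_length(fs$viable_pairs, 3)
  expect_true(fs$functional)

  fs <- failsafe_oxidative(622)  # C624 rescues part P3
  expect_setequal(fs$intact_parts, c("P1", "P2", "P3"))
  expect_true(fs$functional)

  fs <- failsafe_oxidative(c(226, 622, 624))
  expect_identical(fs$intact_parts, "P2")
  expect_false(fs$functional)

  expect_warning(failsafe_oxidative(c(622, 999)), "ignoring")
})

test_that("fail-safe agrees with direct part counting on all 16 loss subsets", {
  res <- c(226, 613, 622, 624)
  parts <- list(226, 613, c(622, 624))
  for (i in 0:15) {
    lost <- res[as.logical(bitwAnd(i, c(1, 2, 4, 8)))]
    fs <- failsafe_oxidative(lost)
    n_intact <- sum(vapply(parts, function(p)
      length(setdiff(p, lost)) > 0, logical(1)))
    expect_identical(fs$functional, n_intact >= 2)
    expect_equal(length(fs$viable_pairs), choose(length(fs$intact_parts), 2))
  }
})

test_that("losing more residues never restores the fail-safe", {
  res <- c(226, 613, 622, 624)
  for (i in 0:15) {
    lost <- res[as.logical(bitwAnd(i, c(1, 2, 4, 8)))]
    f0 <- failsafe_oxidative(lost)$functional
    for (extra in setdiff(res, lost)) {
      expect_false(!f0 && failsafe_oxidative(c(lost, extra))$functional)
    }
  }
})

test_that("inducer-class responsiveness follows the cysteine requirements", {
  expect_false(electrophile_response("I", 151))
  expect_true(electrophile_response("I", c(226, 613)))
  expect_true(electrophile_response("II", 151))
  expect_false(electrophile_response("II", 288))
  expect_true(electrophile_response("III", 151))
  expect_true(electrophile_response("III", c(151, 273)))
  expect_false(electrophile_response("III", c(151, 273, 288)))
  expect_true(electrophile_response("IV", 151))
  expect_false(electrophile_response("IV", c(226, 613)))
  expect_true(electrophile_response("IV", 622))
})

test_that("category counts match elementwise classification", {
  seven <- lapply(observed_variant_strings, parse_protein_variant)
  counts <- count_by_category(seven)
  expect_equal(counts$oxidative_affecting, 7)
  expect_equal(unname(counts$counts[["oxidative_sensor_cys"]]), 3)
  expect_equal(unname(counts$counts[["oxidative_neighbor_basic"]]), 4)
  expect_equal(unname(counts$counts[["electrophile_sensor_cys"]]), 0)

  expect_equal(sum(count_by_category(list())$counts), 0)

  decoy_tab <- generate_variant_table(n_decoys = 10, seed = 4)
  all_vars <- lapply(decoy_tab$protein_change, parse_protein_variant)
  counts <- count_by_category(all_vars)
  expect_equal(counts$oxidative_affecting, 7)
  expect_equal(unname(counts$counts[["non_sensor"]]), 10)
})
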