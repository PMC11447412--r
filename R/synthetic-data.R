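## Seeded synthetic datasets with the statistical structure the analysis
## assumes: graded-dosage calibration series, stress-cohort mRNA
## measurements generated under a chosen ground-truth hypothesis, and
## variant tables. Noise is lognormal-multiplicative (RT-qPCR fold-changes
## are ratio-scale), mean-one on the log scale. Each table draws from its
## own seed stream derived from the root seed, so adding one table does not
## shift the draws of another.

## The seven human KEAP1 oxidative-sensor variants used as the positive set.
KEAP1_OBSERVED_VARIANTS <- c("His225Tyr", "Arg614Gly", "Arg614Trp",
                             "Arg614Gln", "Cys622Ser", "Cys622Arg",
                             "Cys624Tyr")

#' Ground truth for synthetic data generation
#'
#' Container for the simulation truth: the log-log calibration slope, the
#' stressed inactivated fraction of the WT-homodimer pool, the mechanistic
#' hypothesis and heterodimer arithmetic generating the cohort, the
#' multiplicative noise level, replicate counts and the root seed.
#'
#' Defaults mirror the study conditions: dosage levels 100/40/19/5% with 6
#' replicates per level in the calibration series, 5 replicates per cohort
#' group, a unit-magnitude repression slope, and 74% stress inactivation.
#' `noise_sd_log = 0.10` corresponds to a ~10% coefficient of variation in
#' fold-changes, a typical RT-qPCR replicate scatter.
#'
#' @param curve_slope log-log slope of the true calibration curve (< 0).
#' @param f_inact_true stressed inactivated fraction of the WT-homodimer
#'   pool, in \[0, 1\].
#' @param hypothesis_true,mode_true mechanism generating heterodimer
#'   inactivation in the cohort (see [inactivation_setting()]).
#' @param noise_sd_log standard deviation of the lognormal measurement
#'   noise on the log scale (>= 0).
#' @param n_replicates replicates per cohort condition (>= 2).
#' @param n_calib_replicates replicates per calibration dosage level.
#' @param seed root RNG seed.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(curve_slope = -1, f_inact_true = 0.74,
                         hypothesis_true = c("monomer", "dimer"),
                         mode_true = c("paper_linear", "binomial"),
                         noise_sd_log = 0.10, n_replicates = 5,
                         n_calib_replicates = 6, seed = 1) {
  if (curve_slope >= 0) stop("curve_slope must be negative", call. = FALSE)
  if (noise_sd_log < 0) stop("noise_sd_log must be >= 0", call. = FALSE)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  structure(
    list(curve_slope = curve_slope,
         f_inact_true = check_fraction(f_inact_true, "f_inact_true"),
         hypothesis_true = match.arg(hypothesis_true),
         mode_true = match.arg(mode_true),
         noise_sd_log = noise_sd_log,
         n_replicates = as.integer(n_replicates),
         n_calib_replicates = as.integer(n_calib_replicates),
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  calibration slope %s; f_inact %s; %s hypothesis (%s mode)\n",
              format(x$curve_slope), format(x$f_inact_true),
              x$hypothesis_true, x$mode_true))
  cat(sprintf("  noise sd (log) %s; %d cohort / %d calibration replicates; seed %d\n",
              format(x$noise_sd_log), x$n_replicates, x$n_calib_replicates,
              x$seed))
  invisible(x)
}

## True mRNA fold-change at a residual activity fraction, under the
## ground-truth power law anchored at (100%, 1.0-fold).
#' @noRd
truth_mrna_at_activity <- function(truth, activity) {
  activity^truth$curve_slope
}

#' Generate a graded-dosage calibration dataset
#'
#' One noisy measurement table per the graded KEAP1 series: for each dosage
#' level and replicate, `mrna = (level/100)^slope * exp(eps)` with
#' `eps ~ N(0, noise_sd_log^2)`. Deterministic for a fixed truth seed.
#'
#' @param truth a [ground_truth()].
#' @param levels KEAP1 dosage levels in percent (default the study series
#'   100/40/19/5).
#' @param gene gene label for the table.
#' @return a data frame with columns `gene`, `genotype_label`,
#'   `keap1_level_pct`, `mrna_rel`, `replicate_id`.
#' @export
generate_calibration_dataset <- function(truth, levels = c(100, 40, 19, 5),
                                         gene = "Nqo1") {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  n_rep <- truth$n_calib_replicates
  grid <- expand.grid(replicate_id = seq_len(n_rep),
                      keap1_level_pct = levels)
  mu <- log((grid$keap1_level_pct / 100)^truth$curve_slope)
  eps <- with_seed(derive_seed(truth$seed, "calibration"),
                   stats::rnorm(nrow(grid), 0, truth$noise_sd_log))
  data.frame(
    gene = gene,
    genotype_label = sprintf("keap1_%gpct", grid$keap1_level_pct),
    keap1_level_pct = grid$keap1_level_pct,
    mrna_rel = exp(mu + eps),
    replicate_id = grid$replicate_id,
    stringsAsFactors = FALSE
  )
}

#' Generate a stress-cohort observation table
#'
#' For each genotype, the dimer population follows random pairing at its WT
#' allele fraction; total residual activity follows the ground-truth
#' hypothesis, mode and inactivated fraction; expected mRNA follows the
#' ground-truth curve; replicates add lognormal noise.
#'
#' @param truth a [ground_truth()].
#' @param genotypes data frame with columns `label` and
#'   `wt_allele_fraction`; the default holds the stressed all-WT condition
#'   and the stressed balanced heterozygote.
#' @param gene gene label.
#' @return a data frame with columns `gene`, `condition_label`,
#'   `wt_allele_fraction`, `true_activity`, `mrna_rel`, `replicate_id`.
#' @export
generate_stress_cohort <- function(truth,
                                   genotypes = data.frame(
                                     label = c("wt_stressed", "het_stressed"),
                                     wt_allele_fraction = c(1, 0.5)),
                                   gene = "Nqo1") {
  stopifnot(inherits(truth, "ground_truth"))
  genotypes <- as.data.frame(genotypes)
  stopifnot(all(c("label", "wt_allele_fraction") %in% names(genotypes)))
  setting <- inactivation_setting(truth$f_inact_true, truth$hypothesis_true,
                                  truth$mode_true)
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    pop <- dimer_composition(genotypes$wt_allele_fraction[[i]])
    act <- predict_total_activity(pop, setting)$total_activity
    data.frame(
      gene = gene,
      condition_label = as.character(genotypes$label[[i]]),
      wt_allele_fraction = genotypes$wt_allele_fraction[[i]],
      true_activity = act,
      mrna_true = truth_mrna_at_activity(truth, act),
      replicate_id = seq_len(truth$n_replicates),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  eps <- with_seed(derive_seed(truth$seed, "cohort"),
                   stats::rnorm(nrow(out), 0, truth$noise_sd_log))
  out$mrna_rel <- out$mrna_true * exp(eps)
  out$mrna_true <- NULL
  out[c("gene", "condition_label", "wt_allele_fraction", "true_activity",
        "mrna_rel", "replicate_id")]
}

#' Generate a protein-variant table
#'
#' Always contains the seven observed human oxidative-sensor variants
#' (His225Tyr, Arg614Gly/Trp/Gln, Cys622Ser, Cys622Arg, Cys624Tyr), plus
#' `n_decoys` synthetic substitutions at positions disjoint from every
#' sensor and neighbour position, with plausible random amino-acid changes
#' and rare allele frequencies. One row per variant and panel; with the
#' default single panel the table has `7 + n_decoys` rows.
#'
#' @param n_decoys number of decoy variants (>= 0).
#' @param seed RNG seed.
#' @param panels panel names to annotate with allele frequencies.
#' @param map a [keap1_sensor_map()] defining the positions decoys avoid.
#' @return a data frame with columns `gene`, `protein_change`, `panel`,
#'   `allele_frequency`.
#' @export
generate_variant_table <- function(n_decoys = 10, seed = 1,
                                   panels = "TMM_54KJPN",
                                   map = keap1_sensor_map()) {
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  reserved <- c(map$oxidative_cys, map$electrophile_cys,
                as.integer(names(map$oxidative_neighbor_basic)))
  changes <- KEAP1_OBSERVED_VARIANTS
  if (n_decoys > 0) {
    decoys <- with_seed(derive_seed(seed, "variants"), {
      pos <- sample(setdiff(10:600, reserved), n_decoys, replace = FALSE)
      aa1 <- unname(AA3)
      vapply(pos, function(p) {
        ref <- sample(aa1, 1)
        alt <- sample(setdiff(aa1, ref), 1)
        ref3 <- names(AA3)[match(ref, AA3)]
        alt3 <- names(AA3)[match(alt, AA3)]
        paste0(ref3, p, alt3)
      }, character(1))
    })
    changes <- c(changes, decoys)
  }
  freqs <- with_seed(derive_seed(seed, "frequencies"),
                     10^stats::runif(length(changes) * length(panels), -6, -4))
  out <- expand.grid(protein_change = changes, panel = panels,
                     stringsAsFactors = FALSE)
  data.frame(gene = "KEAP1", protein_change = out$protein_change,
             panel = out$panel,
             allele_frequency = signif(freqs, 3),
             stringsAsFactors = FALSE)
}
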