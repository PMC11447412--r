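## Random-dimerization population model of KEAP1 and closed-form predictions
## of total E3-ligase activity under the monomer- and dimer-inactivation
## hypotheses.
##
## KEAP1 functions as a homodimer. In a heterozygote carrying one
## sensor-dead allele (e.g. Keap1^C226S&C613S/+), random pairing of the two
## protein products yields three dimer classes whose fractions follow the
## Hardy-Weinberg-like squares of the allelic (monomer) proportions. Under
## oxidative stress the wild-type homodimer pool is partly inactivated; the
## two hypotheses differ in whether modification of one monomer suffices to
## kill a dimer (monomer inactivation) or both monomers must be modified
## (dimer inactivation). Because the mutant monomer cannot be modified, the
## heterodimer discriminates the hypotheses.

#' Dimer-class composition under random monomer pairing
#'
#' Fractions of wild-type homodimers, heterodimers and mutant homodimers in
#' the dimer pool of a genotype, assuming monomers pair at random in
#' proportion to allelic expression. For a balanced heterozygote
#' (`wt_allele_fraction = 0.5`) this gives the 25% / 50% / 25% split.
#'
#' @param wt_allele_fraction fraction of monomers that are wild type, in
#'   \[0, 1\]. Defaults to 0.5 (heterozygote with equal allelic expression).
#' @return an object of class `dimer_population` with fields `f_wt_homo`,
#'   `f_het`, `f_mut_homo` (fractions summing to 1) and
#'   `wt_allele_fraction`.
#' @examples
#' dimer_composition(0.5)
#' @export
dimer_composition <- function(wt_allele_fraction = 0.5) {
  w <- check_fraction(wt_allele_fraction, "wt_allele_fraction")
  out <- structure(
    list(
      f_wt_homo = w^2,
      f_het = 2 * w * (1 - w),
      f_mut_homo = (1 - w)^2,
      wt_allele_fraction = w
    ),
    class = "dimer_population"
  )
  out
}

#' @export
print.dimer_population <- function(x, ...) {
  cat("KEAP1 dimer population (random pairing, WT monomer fraction ",
      format(x$wt_allele_fraction), ")\n", sep = "")
  cat(sprintf("  WT/WT  homodimer : %5.1f%%\n", 100 * x$f_wt_homo))
  cat(sprintf("  WT/mut heterodimer: %5.1f%%\n", 100 * x$f_het))
  cat(sprintf("  mut/mut homodimer: %5.1f%%\n", 100 * x$f_mut_homo))
  invisible(x)
}

#' @noRd
check_dimer_population <- function(population) {
  if (!inherits(population, "dimer_population")) {
    stop("`population` must be created by dimer_composition()", call. = FALSE)
  }
  s <- population$f_wt_homo + population$f_het + population$f_mut_homo
  if (abs(s - 1) > 1e-12 ||
      any(c(population$f_wt_homo, population$f_het, population$f_mut_homo) < 0)) {
    stop("dimer population fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  population
}

#' Inactivated fraction of the wild-type homodimer pool
#'
#' Complement of the residual activity measured in the all-wild-type
#' stressed animal: if the calibration curve places residual KEAP1 activity
#' at 26% of baseline, 74% of the wild-type homodimer pool has been
#' inactivated by the stress.
#'
#' @param activity_wt_animal residual KEAP1 activity in the all-WT stressed
#'   condition, as a fraction in \[0, 1\].
#' @return the inactivated fraction `1 - activity_wt_animal`.
#' @examples
#' infer_homodimer_inactivation(0.26)  # 0.74
#' @export
infer_homodimer_inactivation <- function(activity_wt_animal) {
  a <- check_fraction(activity_wt_animal, "activity_wt_animal")
  1 - a
}

#' Stress-inactivation setting
#'
#' Bundles the empirically calibrated wild-type-homodimer inactivated
#' fraction with the mechanistic hypothesis and the arithmetic mode used for
#' the heterodimer term.
#'
#' Modes: `"paper_linear"` applies the halving rule — under the monomer
#' hypothesis half of the homodimer-level inactivated fraction is carried
#' over to the heterodimer (its single modifiable monomer). `"binomial"`
#' instead back-solves the per-monomer modification probability p from
#' 1 - (1 - p)^2 = f_inact and uses p for the heterodimer.
#'
#' @param f_inact fraction of the WT-homodimer pool inactivated by the
#'   stress, in \[0, 1\] (see [infer_homodimer_inactivation()]).
#' @param hypothesis `"monomer"` (one modified monomer kills the dimer) or
#'   `"dimer"` (both monomers must be modified).
#' @param mode `"paper_linear"` (default) or `"binomial"`.
#' @return an object of class `inactivation_setting`.
#' @export
inactivation_setting <- function(f_inact,
                                 hypothesis = c("monomer", "dimer"),
                                 mode = c("paper_linear", "binomial")) {
  f <- check_fraction(f_inact, "f_inact")
  structure(
    list(
      f_inact = f,
      hypothesis = match.arg(hypothesis),
      mode = match.arg(mode)
    ),
    class = "inactivation_setting"
  )
}

#' @export
print.inactivation_setting <- function(x, ...) {
  cat(sprintf("inactivation setting: f_inact = %s, %s hypothesis, %s mode\n",
              format(x$f_inact), x$hypothesis, x$mode))
  invisible(x)
}

#' Fraction of heterodimers inactivated by the stress
#'
#' Under the dimer-inactivation hypothesis the heterodimer can never be
#' inactivated (its mutant member carries no functional sensor), so the
#' fraction is 0 in both modes. Under the monomer-inactivation hypothesis
#' the heterodimer is killed when its single wild-type monomer is modified:
#' the linear rule takes half of `f_inact`; the binomial rule takes the
#' per-monomer probability p = 1 - sqrt(1 - f_inact).
#'
#' @param setting an [inactivation_setting()].
#' @return a fraction in \[0, 1\].
#' @examples
#' heterodimer_inactivated_fraction(inactivation_setting(0.74))  # 0.37
#' @export
heterodimer_inactivated_fraction <- function(setting) {
  stopifnot(inherits(setting, "inactivation_setting"))
  if (setting$hypothesis == "dimer") {
    return(0)
  }
  switch(setting$mode,
    paper_linear = setting$f_inact / 2,
    binomial = 1 - sqrt(1 - setting$f_inact)
  )
}

#' Predicted total KEAP1 activity of a mixed dimer population
#'
#' Sums per-dimer-class activity contributions: mutant homodimers are fully
#' active under oxidative stress (their sensors cannot be modified),
#' wild-type homodimers retain the empirically calibrated fraction
#' `1 - f_inact` (hypothesis-independent), and heterodimers retain
#' `1 - heterodimer_inactivated_fraction(setting)`.
#'
#' @param population a [dimer_composition()] result.
#' @param setting an [inactivation_setting()].
#' @return an object of class `activity_prediction` with `total_activity`,
#'   per-class contributions `contrib_mut_homo`, `contrib_wt_homo`,
#'   `contrib_het` (all fractions of baseline activity), and the inputs.
#' @examples
#' predict_total_activity(dimer_composition(0.5),
#'                        inactivation_setting(0.74, "monomer"))
#' @export
predict_total_activity <- function(population, setting) {
  check_dimer_population(population)
  stopifnot(inherits(setting, "inactivation_setting"))
  het_inact <- heterodimer_inactivated_fraction(setting)
  contrib_mut <- population$f_mut_homo
  contrib_wt <- population$f_wt_homo * (1 - setting$f_inact)
  contrib_het <- population$f_het * (1 - het_inact)
  total <- contrib_mut + contrib_wt + contrib_het
  structure(
    list(
      total_activity = total,
      contrib_mut_homo = contrib_mut,
      contrib_wt_homo = contrib_wt,
      contrib_het = contrib_het,
      setting = setting,
      population = population
    ),
    class = "activity_prediction"
  )
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(sprintf("Predicted total KEAP1 activity: %.1f%% (%s hypothesis, %s mode, f_inact = %s)\n",
              100 * x$total_activity, x$setting$hypothesis, x$setting$mode,
              format(x$setting$f_inact)))
  cat(sprintf("  mut/mut homodimers: %5.2f%%\n", 100 * x$contrib_mut_homo))
  cat(sprintf("  WT/WT homodimers  : %5.2f%%\n", 100 * x$contrib_wt_homo))
  cat(sprintf("  WT/mut heterodimers: %5.2f%%\n", 100 * x$contrib_het))
  invisible(x)
}

#' Evaluate the monomer- and dimer-inactivation hypotheses
#'
#' Computes the predicted total activity under both hypotheses (shared
#' `f_inact` and mode) and checks each prediction against the confidence
#' interval of an activity estimate. The selected hypothesis is the one
#' whose prediction lies inside the interval; `"both"` or `"neither"` when
#' the interval is uninformative.
#'
#' @param population a [dimer_composition()] result.
#' @param f_inact inactivated fraction of the WT-homodimer pool.
#' @param estimate an `activity_estimate` (see [estimate_activity_ci()]) or
#'   any list with fields `activity_point`, `ci_low`, `ci_high` on the
#'   fraction scale.
#' @param mode heterodimer arithmetic mode, `"paper_linear"` or
#'   `"binomial"`.
#' @return an object of class `hypothesis_verdict` with the two
#'   predictions, per-hypothesis CI membership, and `selected` in
#'   `{"monomer", "dimer", "both", "neither"}`.
#' @export
evaluate_hypotheses <- function(population, f_inact, estimate,
                                mode = c("paper_linear", "binomial")) {
  mode <- match.arg(mode)
  check_dimer_population(population)
  est <- estimate
  need <- c("activity_point", "ci_low", "ci_high")
  if (!is.list(est) || !all(need %in% names(est))) {
    stop("`estimate` must carry activity_point, ci_low and ci_high",
         call. = FALSE)
  }
  if (!all(vapply(est[need], function(v) is.finite(v), logical(1)))) {
    stop("`estimate` must carry a finite confidence interval", call. = FALSE)
  }
  if (est$ci_low > est$ci_high) {
    stop("degenerate confidence interval: ci_low > ci_high", call. = FALSE)
  }
  pred_mono <- predict_total_activity(
    population, inactivation_setting(f_inact, "monomer", mode))
  pred_dim <- predict_total_activity(
    population, inactivation_setting(f_inact, "dimer", mode))
  ## tolerance guards the comparison against floating-point noise only
  tol <- 1e-9
  inside <- function(p) est$ci_low - tol <= p && p <= est$ci_high + tol
  within_ci <- c(monomer = inside(pred_mono$total_activity),
                 dimer = inside(pred_dim$total_activity))
  selected <- if (within_ci[["monomer"]] && within_ci[["dimer"]]) {
    "both"
  } else if (within_ci[["monomer"]]) {
    "monomer"
  } else if (within_ci[["dimer"]]) {
    "dimer"
  } else {
    "neither"
  }
  structure(
    list(
      prediction_monomer = pred_mono$total_activity,
      prediction_dimer = pred_dim$total_activity,
      breakdown_monomer = pred_mono,
      breakdown_dimer = pred_dim,
      estimate = est,
      within_ci = within_ci,
      selected = selected,
      mode = mode,
      f_inact = check_fraction(f_inact, "f_inact")
    ),
    class = "hypothesis_verdict"
  )
}

#' @export
print.hypothesis_verdict <- function(x, ...) {
  cat("KEAP1 dimer-inactivation hypothesis test\n")
  cat(sprintf("  observed activity: %.1f%%  (95%% CI %.1f%% - %.1f%%)\n",
              100 * x$estimate$activity_point, 100 * x$estimate$ci_low,
              100 * x$estimate$ci_high))
  cat(sprintf("  monomer-inactivation prediction: %.1f%%  [%s]\n",
              100 * x$prediction_monomer,
              if (x$within_ci[["monomer"]]) "inside CI" else "outside CI"))
  cat(sprintf("  dimer-inactivation prediction  : %.1f%%  [%s]\n",
              100 * x$prediction_dimer,
              if (x$within_ci[["dimer"]]) "inside CI" else "outside CI"))
  cat(sprintf("  selected: %s\n", x$selected))
  invisible(x)
}
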