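## Independent oracles used across test files. These deliberately avoid the
## package's analytic code paths.

## Exact power-law calibration table: mrna = (100/level)^|slope|, optionally
## replicated.
make_power_law_calibration <- function(levels = c(100, 40, 19, 5),
                                       slope_mag = 1, n_rep = 1) {
  d <- expand.grid(replicate_id = seq_len(n_rep), keap1_level_pct = levels)
  data.frame(keap1_level_pct = d$keap1_level_pct,
             mrna_rel = (100 / d$keap1_level_pct)^slope_mag,
             replicate_id = d$replicate_id)
}

## Monte-Carlo oracle for total dimer-pool activity: simulate individual
## dimers of a (25/50/25) population, modify monomers (or whole dimers for
## the linearized modes) stochastically, and count active dimers. Returns
## the estimate and its standard error.
mc_total_activity <- function(f_inact, hypothesis, mode, n = 1e6,
                              pop = c(wt = 0.25, het = 0.5, mut = 0.25)) {
  n_wt <- round(n * pop[["wt"]])
  n_het <- round(n * pop[["het"]])
  n_mut <- n - n_wt - n_het
  if (mode == "binomial") {
    ## coherent per-monomer modification probability
    p <- if (hypothesis == "monomer") 1 - sqrt(1 - f_inact) else sqrt(f_inact)
    mod_wt_a <- stats::rbinom(n_wt, 1, p)
    mod_wt_b <- stats::rbinom(n_wt, 1, p)
    mod_het_wt <- stats::rbinom(n_het, 1, p)  # the mutant member is inert
    if (hypothesis == "monomer") {
      active_wt <- (mod_wt_a + mod_wt_b) == 0
      active_het <- mod_het_wt == 0
    } else {
      active_wt <- (mod_wt_a * mod_wt_b) == 0
      active_het <- rep(TRUE, n_het)
    }
  } else {
    ## linearized rule operates at the dimer level
    active_wt <- stats::rbinom(n_wt, 1, 1 - f_inact) == 1
    p_het <- if (hypothesis == "monomer") f_inact / 2 else 0
    active_het <- stats::rbinom(n_het, 1, 1 - p_het) == 1
  }
  active <- c(active_wt, active_het, rep(TRUE, n_mut))
  c(est = mean(active), se = stats::sd(active) / sqrt(length(active)))
}

## Brute-force dimer composition for a rational allele fraction k/m:
## enumerate all ordered pairs of monomers and collapse symmetric
## heterodimers.
enumerate_dimer_composition <- function(k, m) {
  monomers <- c(rep("W", k), rep("M", m - k))
  pairs <- expand.grid(a = monomers, b = monomers, stringsAsFactors = FALSE)
  type <- paste0(pmin(pairs$a, pairs$b), pmax(pairs$a, pairs$b))
  tab <- table(factor(type, levels = c("WW", "MW", "MM"))) / nrow(pairs)
  as.numeric(tab)  # (wt homo, het, mut homo)
}

## The seven observed human oxidative-sensor variants.
observed_variant_strings <- c("His225Tyr", "Arg614Gly", "Arg614Trp",
                              "Arg614Gln", "Cys622Ser", "Cys622Arg",
                              "Cys624Tyr")
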