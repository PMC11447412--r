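---
title: "Methods: dimer-inactivation inference and sensor-variant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer-inactivation inference and sensor-variant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keapsense)
```

## The scientific question

KEAP1 represses NRF2 as an obligate homodimer whose sensor cysteines are
covalently modified by stress. Because both members of the dimer carry
sensors, two mechanisms are conceivable: a single modified monomer
inactivates the whole dimer (*monomer inactivation*), or both monomers must
be modified (*dimer inactivation*). A heterozygote expressing one
sensor-dead allele discriminates them: its heterodimers carry exactly one
modifiable monomer, so the two mechanisms predict different total residual
activities under stress. `keapsense` turns that design into a reusable
statistical pipeline.

## Dimer population model

Monomers pair at random in proportion to allelic expression. With
wild-type monomer fraction $w$, the dimer pool is

$$f_\mathrm{WT/WT} = w^2,\qquad f_\mathrm{WT/mut} = 2w(1-w),\qquad
  f_\mathrm{mut/mut} = (1-w)^2 .$$

`dimer_composition()` implements this; the default $w = 0.5$ models a
heterozygote with equal allelic expression, and unequal expression is
supported through `wt_allele_fraction`. The fractions are validated to sum
to one within $10^{-12}$.

**Assumptions.** Dimerization is random and complete (no monomer pool, no
preferential homo- or hetero-pairing), both alleles are expressed at equal
protein dosage by default, and dimers do not exchange subunits on the
timescale of the measurement.

## Activity under stress

Let $f$ be the fraction of the *wild-type homodimer* pool inactivated by
the stress. It is not assumed: it is inferred from the all-wild-type
stressed animal as the complement of its calibrated residual activity
(`infer_homodimer_inactivation()`). Total predicted activity sums
per-dimer-class contributions (`predict_total_activity()`):

* mutant homodimers contribute their full share $f_\mathrm{mut/mut}$ —
  their sensors cannot be modified, and they repress basal NRF2 normally;
  no partial-activity parameter is exposed;
* wild-type homodimers contribute $f_\mathrm{WT/WT}(1-f)$. This term is
  *hypothesis-independent* because $f$ is calibrated empirically at the
  dimer level from the all-WT animal;
* heterodimers contribute $f_\mathrm{WT/mut}(1-h)$, where $h$ is the
  heterodimer inactivated fraction given by
  `heterodimer_inactivated_fraction()`.

Under dimer inactivation $h = 0$ identically: the mutant member can never
be modified, so the "both members hit" condition is unsatisfiable. Under
monomer inactivation two arithmetic modes are provided:

* `paper_linear` (default): $h = f/2$ — the heterodimer carries half the
  modifiable monomers of a WT homodimer, so it is credited half the
  homodimer-level inactivation. This linearization reproduces the familiar
  back-of-envelope arithmetic exactly (with $f = 0.74$ and a 25/50/25
  population: heterodimer inactivation 37%, contributions 25% + 6.5% +
  31.5%, totals 63% vs 81.5%), which is why it is the default.
* `binomial`: solves $1-(1-p)^2 = f$ for the per-monomer modification
  probability $p = 1-\sqrt{1-f}$ and sets $h = p$. This is the coherent
  per-monomer model; it always predicts less heterodimer activity than the
  linear rule (equality only at $f = 0$).

Whether the halving rule is an approximation of a binomial process or a
distinct mechanistic assumption is genuinely open; the package provides
both and asserts neither as true. Monte-Carlo simulation of individual
dimers (used as an independent oracle in the test suite, $10^6$ dimers per
setting over $f \in \{0.1,\dots,0.9\}$) confirms the closed forms for every
hypothesis × mode combination.

`evaluate_hypotheses()` computes both predictions and checks each against
the confidence interval of the measured activity; the verdict is
`monomer`, `dimer`, `both` or `neither` by literal CI membership. The
membership comparison uses a $10^{-9}$ guard against floating-point noise
only — it is not a scientific tolerance.

## Calibration curve

The dosage–response relation is modelled as a power law,

$$\log M = \alpha + \beta \log(L/100), \qquad \beta < 0,$$

with $M$ the target-gene fold-change and $L$ the KEAP1 level in percent of
wild type. The form is a deliberate design choice: it is the minimal
two-parameter monotone family consistent with the anchor behaviour of the
graded-dosage series (100% dosage at 1.0-fold baseline; strong induction at
low dosage), it is linear in log-log space so ordinary least squares
applies, and it is analytically invertible. A monotone-spline alternative
is explicitly out of scope.

`fit_calibration()` requires at least two distinct positive dosage levels
(the minimum identifying the two parameters) and rejects fits with
$\beta \ge 0$: the model presumes repression, and a non-inverse
relationship indicates data or labelling problems rather than a fittable
curve. The baseline is anchored multiplicatively: fold-change 1.0 is
defined by the wild-type group's *geometric* mean, matching the
multiplicative noise model. The fit is scale-equivariant — rescaling all
fold-changes shifts $\alpha$ only and leaves inverted activities unchanged.

Inversion (`invert_activity()`) solves the fitted curve exactly. Observed
fold-changes below the fitted baseline would imply activity above 100%;
they are clipped to 100% with a warning, since residual activity is
reported as a fraction of the wild-type pool. The noiseless round trip
`invert(predict(x)) = x` holds to $10^{-9}$ across the dosage range.

## Bootstrap confidence intervals

`estimate_activity_ci()` propagates both error sources:

1. calibration uncertainty — calibration points are resampled with
   replacement *stratified by dosage level*, so every level keeps its
   replicate count and no resample degenerates to a single level;
2. measurement uncertainty — the observed replicates are resampled with
   replacement; their geometric mean is inverted through the refitted
   curve.

Because the stratified design fixes the dosage levels, the refit depends
on the resampled per-level response means only; the implementation
exploits this closed form to vectorize the whole bootstrap (default
`n_boot = 2000`), making the large repetition studies below cheap. A
resample whose refitted slope is non-negative has no inverse relationship;
such draws are redrawn with a capped retry and the estimator errors out if
they dominate.

**Interval form.** The interval is an *expanded percentile* interval: with
$m$ observed replicates, the bootstrap distribution is read at quantiles
$\Phi(\mp z^\ast)$ with
$z^\ast = \sqrt{m/(m-1)}\; t_{m-1,\,0.975}$, rather than at 2.5/97.5%.
The plain percentile interval has two well-known small-sample defects —
resampling $m$ of $m$ values shrinks the bootstrap variance by
$(m-1)/m$, and no t-correction is applied for the estimated scale — which
are material at RT-qPCR group sizes ($m = 5$: the plain interval's
effective two-sided coverage is roughly 87–92% at nominal 95%). The
expansion restores near-nominal coverage while keeping the interval fully
nonparametric and transformation-respecting. Using the observed-replicate
$m$ for the correction is slightly conservative when calibration
uncertainty (which carries more degrees of freedom) dominates; we accept
that asymmetry. The test suite measures empirical coverage across 100
generator seeds at the stressed wild-type operating point.

Estimates are deterministic for a fixed seed, and the caller's RNG state
is never disturbed. Point estimates and intervals are held on the
fraction scale in $[0,1]$ internally; percentages appear only in printed,
human-facing output.

## Synthetic data generator

`ground_truth()` fixes the simulation truth; the generators emulate the
three table dialects the pipeline consumes.

* **Calibration series** (`generate_calibration_dataset()`): dosage levels
  100/40/19/5% (the graded series of wild-type, hemizygous, hypomorphic
  and hypomorphic-knockout livers), 6 replicates per level, responses
  $M = (L/100)^\beta e^\varepsilon$, $\varepsilon \sim N(0,
  \sigma_{\log}^2)$. The intermediate levels' true responses are
  interpolated from the ground-truth curve; their published per-level
  values are figure-only and not reproduced numerically.
* **Stress cohort** (`generate_stress_cohort()`): for each genotype the
  dimer population, its total activity under the ground-truth hypothesis,
  and the expected mRNA through the ground-truth curve; 5 replicates per
  condition with the same multiplicative noise. Defaults hold the stressed
  all-WT condition and the stressed balanced heterozygote.
* **Variant table** (`generate_variant_table()`): always the seven
  observed human oxidative-sensor variants, plus seeded decoy
  substitutions at positions disjoint from every sensor and neighbour
  position, with rare allele frequencies carried as annotations.

Noise is lognormal and mean-one on the log scale, reflecting the
ratio-scale nature of RT-qPCR fold-changes; per-group geometric means
converge to the noiseless curve (verified over 1000 seeds in the tests).
Each table draws from its own seed stream derived from the root seed, so
generating one table never shifts another's draws.

**Noise default.** `noise_sd_log = 0.10` (≈10% coefficient of variation
per replicate) is the package's choice of a realistic replicate scatter
for RT-qPCR fold-changes, fixed a priori from a design analysis: the two
hypothesis predictions sit 18.5 percentage points apart, and discrimination
at ≥90% frequency with $m = 5$ replicates requires the activity CI
half-width to stay below roughly ±10 points. At the default, heterozygote
CIs come out near ±6–9 points. A half-width near ±13 points — the order
reported for the real cohort, which carries biological between-animal
variance this generator does not model — would place the dimer prediction
inside the interval in a substantial fraction of cohorts and make the two
mechanisms statistically inseparable at this design size. Users wanting
the harder regime can raise `noise_sd_log`; the generator parameter is a
modelling input, not a fitted quantity.

**What the generator does not emulate:** biological between-animal
variance beyond the replicate noise, qPCR efficiency and
normalization-gene effects, survival/censoring structure, RNA-seq counts,
and linkage between variants. Passing recovery tests therefore show the
*inference machinery* is sound at the stated noise level and design size,
not that real cohorts carry this little variance.

## Pipeline and reports

`run_dimer_analysis()` chains fit → per-condition activity estimation →
inactivation inference (from the configured all-WT stressed condition;
its absence is a configuration error detected before computation) →
both-hypothesis prediction → verdict. `run_variant_screen()` chains parse
→ classify → single-variant fail-safe evaluation → category counts;
malformed rows are collected and reported, and only a table with zero
parseable rows fails. Reports serialize to JSON (sorted keys, a config
hash over the analytic inputs, the seed and package version for audit)
and TSV; re-running an identical configuration is byte-identical. The
package's interface is its exported functions; configurations can also be
read from YAML files with `read_config()`.

## Sensor map and fail-safe semantics

The default `keap1_sensor_map()` uses the conventional sensor numbering
(oxidative 226/613/622/624 with basic neighbours His225 and Arg614;
electrophile 151/273/288) applied to both mouse and human KEAP1; every
entry is an argument, so species offsets or extended neighbour windows can
be supplied without code change. Cys622 and Cys624 form one redundant part
(P3): either surviving thiol keeps the part intact, consistent with single
622/624 variants being tolerated in human populations. The fail-safe rule
is purely combinatorial — functional iff at least two of the three parts
are intact, equivalently at least one viable disulfide pair — and is
checked exhaustively over all 16 loss subsets in the tests, along with
monotonicity (losing more residues never restores function). No
"surrounding basic residue" set is defined for the electrophile sensors:
the default map asserts only what is established, and inventing one would
silently change screen counts.

Variants whose reference residue contradicts the map (annotation drift
across transcript versions) classify as `non_sensor` with a warning rather
than erroring, so a screen is never aborted by a stale annotation.

## Numerical and degenerate-input conventions

* Fractions everywhere internally; percentages only at I/O boundaries.
* Population fractions and prediction breakdowns validated to $10^{-12}$.
* Zero-variance data (noiseless calibration, identical replicates)
  produce a degenerate interval equal to the point estimate, not an error.
* Degenerate CIs (`ci_low > ci_high`) supplied to `evaluate_hypotheses()`
  are a validation error.
* Bootstrap resamples with non-negative slope: capped redraw, then error.
* Inverted activities above 100% clip to 100% with a warning; above-one
  bootstrap draws clip likewise before quantiles are taken.

## Problem sizes used in the shipped studies

The repetition studies in the test suite use 100 generator seeds for CI
coverage, 200 seeded cohorts per ground-truth hypothesis for recovery, and
$10^6$ simulated dimers per Monte-Carlo comparison — sizes chosen so each
study's Monte-Carlo error is small against the margin it checks while the
whole suite stays fast enough to run routinely.

## Known limitations

* The calibration functional form is asserted, not selected; data with a
  genuinely non-power-law dosage response would be mis-inverted (the fit
  diagnostics in `summary()` are the guard).
* The linear heterodimer rule and the binomial rule bracket plausible
  mechanisms but neither models cooperative or time-resolved modification;
  kinetic modelling of dimer exchange is out of scope.
* The inactivated fraction $f$ is a single number per stress condition;
  dose-response of the stress itself is not modelled.
* The variant screen carries allele frequencies as annotations only and
  performs no population-genetic testing; nucleotide-level consequence
  calling is out of scope.
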