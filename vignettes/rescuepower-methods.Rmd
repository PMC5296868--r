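---
title: "Methods: simulating partial-rescue preclinical trials from natural-history moments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating partial-rescue preclinical trials from natural-history moments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescuepower)
```

## The problem

Knock-in mouse models of slowly progressing neurodegenerative disease — the
motivating case is the heterozygous Q111 huntingtin knock-in (HET) versus
wild type (WT) — show little overt pathology in the first year of life, but
robust molecular changes: down-regulation of striatal signaling transcripts
(*Scn4b*, *Drd1a*, *Cnr1*, *Darpp32*, *Homer1*), accumulation of mutant
huntingtin aggregates in neuronal nuclei, and reduced somatic DARPP32.
Whether these endpoints are usable in an interventional trial is a power
question: given the natural-history distribution of each endpoint at a given
age, how many animals are needed to detect a treatment that *partially*
normalizes the mutant phenotype?

`rescuepower` answers this by simulation. A cross-sectional natural-history
cohort is summarized per design cell (genotype × age × arm) by its mean
vector and covariance matrix over the endpoint panel; hypothetical 2×2
factorial trials (genotype × treatment) are then drawn from multivariate
normal distributions with those moments; a treatment is modeled as a
*partial rescue* that moves the mutant mean toward wild type by a fraction
`r`; and power is the fraction of simulated trials in which the chosen
detection test rejects.

## Data model and moments estimation

A cohort is a tidy table, one row per animal (`animal_id`, `genotype`,
`age_months`, `sex`, `arm`, then one numeric column per endpoint). Moments
are estimated per cell with the unbiased (n − 1) sample covariance. Two
choices here are deliberate:

* **Missing values** are handled by pairwise-complete covariance followed by
  eigenvalue clipping (`repair_psd()`), because a pairwise-complete
  estimate need not be a valid covariance matrix and the simulator requires
  positive semidefiniteness. Clipping at zero is the minimal projection
  onto the PSD cone; it leaves complete-data estimates untouched.
* **Sexes are pooled** by default (the `group_by` argument can add `sex`):
  cross-sectional designs of this type usually balance sexes within cells,
  and pooling doubles the per-cell n available to the covariance estimate,
  which is the quantity the whole pipeline leans on.

The multivariate normal is the modeling assumption, not a claim about the
data: rank-based analyses are provided separately (below) precisely because
several of these endpoints (aggregate counts near the detection floor at
young ages) are far from Gaussian.

## The synthetic default parameterization

`q111_config()` ships a parameterization that emulates the structure of a
Q111 natural-history study so every stage of the pipeline runs without any
external data: ten striatal endpoints (five QRT-PCR transcripts, five IHC
measures), ages 3, 9 and 12 months, n = 9 animals per genotype × age cell.
Standardized genotype effects are zero at 3 months and large at 9–12
months. Exactly one endpoint is anchored to published values: the
aggregate-fraction endpoint (`mhtt_aggregates`, the fraction of neurons
carrying a large intranuclear inclusion) uses Cohen's d of 0, 1.6 and 6.7
at 3, 9 and 12 months. **Every other effect magnitude is a synthetic
placeholder**, chosen once to be plausible for this model class (transcript
effects of d ≈ 1–2.6 at late ages, a weaker and noisier IHC DARPP32 effect,
null effects on cell counts), and the per-endpoint units and SDs are
likewise invented. Endpoints whose expected genotype effects share a sign
are given a moderate positive correlation (0.3); opposite-direction and
null-direction pairs are uncorrelated. The 0.3 default makes the
multivariate endpoint genuinely multivariate — correlated signal endpoints
are partially redundant, so the composite gains less than independent ones
would — without making the covariance ill-conditioned.

What the generator deliberately does **not** emulate: non-Gaussian
marginals (the real aggregate fraction is zero-inflated at 3 months),
age-dependent variances, sex effects, and any within-animal longitudinal
structure (the design is cross-sectional, so cells are independent).
Consequently, tests passing against this generator demonstrate the
correctness and calibration of the *machinery*, not the power of any real
endpoint; power statements about a real study require moments estimated
from that study's data via `estimate_moments()`.

## Reproducibility contract

One user-facing seed drives everything. Per-cell sampling streams are
derived deterministically from `(seed, cell label)`, so a cohort is
byte-identical regardless of the order cells are requested in. Power grids
derive each grid point's stream from `(seed, n_per_arm)` — not from the
rescue fraction — so sweeps along `r` at fixed n share common random
numbers. This is a variance-reduction choice: power curves in `r` are then
monotone up to a small Monte-Carlo wobble instead of crossing themselves,
and adjacent grid points can be compared with far fewer replicates.
Derived seeds are kept below 2^31.

## Natural-history endpoint reporting

`select_and_run()` implements the conventional decision tree: per-group
Anderson–Darling normality and mean-centered Levene homoscedasticity at a
gate level of `alpha_assume = 0.05` (a convention, not an estimate); if both
pass, a two-way ANOVA with sequential sums of squares (order-invariant on
the balanced designs this targets); otherwise Kruskal–Wallis with Dunn's
post-hoc z-tests restricted to the genotype contrast within each age,
Bonferroni-corrected over exactly those comparisons. Groups smaller than 8
cannot support the Anderson–Darling test and fail the gate outright — with
n ≈ 9 per sex this makes the nonparametric branch the default for
sex-stratified analyses, which matches how such data are usually reported.
Degenerate inputs follow fixed conventions rather than erroring: a constant
response yields F = 0 with p = 1 (warned), complete ties yield H = 0 with
p = 1, and the Levene statistic on identically constant groups is W = 0,
p = 1. The two-sample Kolmogorov–Smirnov helper uses the exact permutation
distribution when n1·n2 ≤ 400 and the asymptotic Kolmogorov distribution
otherwise.

For summary tables (analyte panels reported as per-group mean, SD, n), the
pooled-variance Student t-test is used rather than Welch's: at n = 4 per
genotype the pooled test reproduces the printed two-decimal p-values of the
worked plasma panel (`q111_plasma_panel()`), Welch does not. Two of the
printed chemistry rows (creatine, M-CSF-1) are not reproduced by any
two-sample t at the printed summaries — presumably per-analyte n
differences or rounding in the source — and are documented as exclusions
rather than guessed at. Effect sizes are Cohen's d with a
normal-approximation confidence interval,
se(d) = sqrt((n1+n2)/(n1·n2) + d²/(2(n1+n2−2))); the construction is
centralized in `cohens_d_summary()` so an alternative (e.g.
noncentral-t-based) interval could be swapped in. Panel p-values are
reported unadjusted, matching how such safety panels are printed.
Analytes below the assay's lower limit of quantification in every animal
are excluded from testing, never imputed.

## The rescue model and univariate power

`apply_rescue()` adds treated cells to a baseline moments set:
μ(HET, treated) = μ(HET) + r·(μ(WT) − μ(HET)) per endpoint, with the
treated covariance inherited from the baseline heterozygote, and treatment
assumed inert in wild-type animals. Rescue acts on means only — a treatment
that also changes variances is out of scope. The detection test is the
two-sided pooled-variance t contrast of treated versus baseline
heterozygotes at level α (default 0.05); the wild-type arms anchor moment
estimation and classifier training. This contrast is the minimal reading of
"power to detect a partial rescue"; the full genotype × treatment
interaction would be an alternative and the detection step is a small,
replaceable function.

`estimate_power()` reports the detection fraction over `reps` simulated
trials with its Monte-Carlo standard error sqrt(p(1−p)/reps).
`analytic_power()` provides the closed-form check: for a single endpoint
with equal SDs, a rescue of fraction `r` on an endpoint with standardized
genotype effect d is exactly a two-sample t power problem at effective
effect r·d, noncentrality r·d·sqrt(n/2) on 2n − 2 degrees of freedom. The
test suite holds the Monte-Carlo estimate to within 3 MC standard errors of
this oracle.

## The elastic-net composite endpoint

`fit_enet()` fits a penalized logistic regression of genotype on the
standardized endpoints (glmnet's objective, mixing parameter
`alpha_mix = 0.5` by default; λ chosen by 5-fold stratified
cross-validation under the minimum-deviance rule, folds derived from the
seed). Standardization parameters are stored in the model, so composite
scores — the linear predictor, a per-animal log-odds of being mutant — are
invariant to affine rescaling of the inputs with a matching refit. A model
driven to an all-zero weight vector is a constant score: by convention such
a replicate counts as a non-detection, since any other rule would
manufacture detections out of nothing.

For composite-endpoint power (`estimate_power_multi()`), the classifier is
refit on every replicate, so the estimate is honest about model-selection
variability. One design question was genuinely open: *which animals train
the per-replicate classifier?* Training on the trial's own baseline arms is
tempting (no extra animals), but the baseline heterozygotes would then
appear both in the training set and in the detection contrast; their fitted
scores are optimistically shifted relative to the out-of-sample treated
heterozygotes, and the null rejection rate roughly triples at n = 10. The
default therefore draws an independent natural-history-style training
cohort per replicate (`n_train = 18` per genotype, the pooled-sex cell size
of the emulated study), which keeps the null test exactly at level — the
package's calibration tests verify this at 3 MC standard errors — and
mirrors how such classifiers are actually built (trained on natural-history
data, applied to trial animals). The biased variant is retained as
`train = "baseline_arms"` for comparison, and a fixed pre-trained model can
be supplied to skip refitting entirely.

## Numerical choices and degenerate inputs

* Covariances are validated to eigenvalue ≥ −1e−10 before use; estimates
  are repaired by eigenvalue clipping, never silently.
* Summary t-tests with both SDs zero return p = 1 for equal means and a
  flagged p = 0 with a warning otherwise; effect sizes with a zero pooled
  SD are an error (undefined d).
* glmnet is called on pre-standardized inputs with `standardize = FALSE`
  so the stored center/scale are exactly the ones used in fitting;
  convergence threshold 1e−9; a fixed-λ fit is reached along a warm-start
  path ending at the requested value. If the cross-validation path
  collapses on degenerate data (e.g. indistinguishable classes), the fit
  falls back to the fully penalized null model.
* Fold assignment is stratified within class and deterministic given the
  seed; `folds` may not exceed the smaller class.

## Problem sizes used by the test suite

The package's own checks run at sizes chosen to keep the full suite at
desk scale while leaving Monte-Carlo noise well below the tolerances being
asserted: calibration and oracle comparisons use 2 000–5 000 replicates
(MC se ≈ 0.003–0.005 at the null), monotonicity sweeps 300–1 500
replicates per grid point under common random numbers, and the
moment-recovery round trip 100 000 animals per cell (sampling error ≈ 0.1%
on means, well inside the 1%/5% recovery targets). The acceptance script
recomputes the same quantities at the same sizes from a fresh seed.

## Known limitations

* Gaussian cells only; heavy tails, zero inflation and floor effects in
  real endpoints will make the simulated power optimistic for rank-based
  detection and slightly off for t-based detection at small n.
* Cross-sectional cells; no shared animals across ages, no repeated
  measures.
* Equal arm sizes and a single treated dose; no sequential or adaptive
  designs, no survival endpoints.
* The built-in parameterization is a labelled synthetic stand-in. Its
  composite-endpoint power at late ages is driven by the one anchored
  endpoint (d = 6.7 at 12 months) plus eight placeholder effects, so
  grid results from it characterize the machinery, not any real cohort.
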