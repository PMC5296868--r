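# rescuepower

Simulation-based power analysis for preclinical trials in slowly
progressing disease models — written for the common situation where a
knock-in mouse line shows no overt phenotype but robust molecular changes
(transcript down-regulation, protein aggregates) whose natural history has
been characterized cross-sectionally, and the question is whether a
planned 2×2 factorial trial (genotype × treatment) can detect a treatment
that *partially* normalizes those endpoints.

Its intended users are biostatisticians and experimentalists planning
interventional studies in such models; the motivating system is the
heterozygous Q111 huntingtin knock-in mouse (HET) versus wild type (WT),
with striatal QRT-PCR and immunohistochemistry endpoints.

## The model

A natural-history cohort is summarized per design cell (genotype × age ×
arm) by the mean vector μ and covariance matrix Σ of its endpoint panel;
simulated animals are drawn from N(μ, Σ). A treatment with **rescue
fraction** r ∈ [0, 1] acts on the mutant mean only:

    μ(HET, treated) = μ(HET) + r · (μ(WT) − μ(HET)),   Σ(HET, treated) = Σ(HET)

with treatment inert in wild-type arms. Detection is the two-sided
pooled-variance t contrast of treated vs baseline heterozygotes at level
α, and power is estimated over Monte-Carlo replicates with standard error
√(p(1−p)/reps). For a single endpoint with standardized genotype effect d,
the closed-form cross-check is the noncentral-t power at effective effect
r·d (`analytic_power()`). A multivariate **composite endpoint** is the
linear predictor of an elastic-net logistic classifier of genotype
(glmnet; α_mix = 0.5, λ by stratified 5-fold CV), refit per replicate on
an independent natural-history-style training draw; a fitted model with no
nonzero weights counts as a non-detection.

The package also covers the surrounding reporting workflow:
summary-statistics pooled t-tests and Cohen's d with CIs for analyte
panels (with lower-limit-of-quantification censoring), and the
assumption-gated omnibus/post-hoc decision tree (Anderson–Darling +
Levene, then two-way ANOVA or Kruskal–Wallis with Dunn/Bonferroni), plus a
two-sample Kolmogorov–Smirnov helper with exact small-sample p-values.

## Worked example

```r
library(rescuepower)

# Built-in synthetic parameterization emulating a Q111 natural-history
# study (10 endpoints; only the aggregate-fraction effect sizes 0/1.6/6.7
# at 3/9/12 months are anchored to published values, the rest are labelled
# placeholders):
m <- config_moments(q111_config())

# 1. Summary-statistics analysis of the bundled 12-month plasma panel
analyze_panel(q111_plasma_panel()) |> head(3)
#>   analyte        t     p      d ci_low ci_high
#> 1 EGF       -0.498 0.636  0.352  -1.05   1.75
#> 2 Eotaxin    1.52  0.180 -1.07   -2.58   0.441
#> 3 IL-1 beta -0.385 0.714  0.272  -1.12   1.67

# 2. Univariate power: 50% rescue of the Scn4b transcript at 12 months,
#    10 animals per arm
estimate_power(m, "scn4b", rescue_model(0.5), trial_design(n_per_arm = 10),
               reps = 2000, seed = 1)
#>   endpoint     r n_per_arm power   mc_se
#> 1 scn4b      0.5        10 0.805 0.00886

# 3. Composite-endpoint power over a small design grid
grid <- power_grid(m, r_grid = c(0.25, 0.5), n_grid = c(10, 20),
                   reps = 200, seed = 1)
grid[c("r", "n_per_arm", "power", "mc_se")]
#>       r n_per_arm power   mc_se
#> 1  0.25        10 0.8   0.0283
#> 2  0.25        20 0.995 0.00499
#> 3  0.5         10 1     0
#> 4  0.5         20 1     0
autoplot(grid)   # power curves vs r, one ribbon per arm size
```

Reading the output: at this parameterization a 50% rescue of *Scn4b*
(genotype d = 2.6 at 12 months, so an effective standardized effect of
1.3) is detected in ~80% of trials with 10 animals per arm, and the
multivariate composite reaches ≥80% power already at a 25% rescue — the
design argument for combining endpoints. Because eight of the ten
endpoint effects are synthetic placeholders, these numbers characterize
the machinery; rerun with `estimate_moments()` on your own cohort for real
design values.

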