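# alphasupp

Visuocortical alpha suppression analysis for differential conditioning EEG.

## The problem

In differential threat conditioning, a visual stimulus paired with an
aversive outcome (CS+) comes to capture visual attention, and one
electrophysiological signature of that capture is event-related
desynchronization (ERD) of occipital alpha-band (8–12 Hz) activity:
stimulus-locked alpha power drops more strongly for CS+ than for unpaired
control stimuli (CS−). Testing whether this conditioned alpha suppression
survives a day's delay — and whether extinction training undoes it — requires
a fairly long analysis chain, each link of which has parameters that matter:

1. **Surface Laplacian (current source density, CSD).** Spherical-spline
   interpolation of the scalp potential, evaluated as its (negative) surface
   Laplacian: reference-free, spatially sharpened signals consistent with
   visuocortical sources. Kernels
   `g(x) = (1/4π) Σₙ (2n+1)/(n(n+1))ᵐ Pₙ(x)` and
   `h(x) = (1/4π) Σₙ (2n+1)/(n(n+1))^{m−1} Pₙ(x)` with spline order `m = 4`,
   maximum Legendre degree `N = 10`, regularization `λ = 1e−5`.
2. **Time–frequency power.** Complex Morlet wavelets with variable
   bandwidth (`m_w = f/σ_f = 12`) on a 3.8–30.4 Hz grid in 0.38 Hz steps,
   after time-domain baseline subtraction (−600…−500 ms) and a
   cosine-square taper (20-sample flanks).
3. **Percent-change normalization.** Condition-averaged power divided by its
   pre-stimulus (−400…−200 ms) mean: `100·(P/P_base − 1)`.
4. **Inference.** Alpha (8.1–11.9 Hz) power over the occipital ROI
   (Oz, POz, O1, O2) in 500–1200 ms feeds a 2×2 within-subject ANOVA
   (Contingency × Extinction) with partial η², a Bayesian mixed-model
   comparison (four fixed-effect structures vs. a subject-only null, scaled
   g-priors, inclusion Bayes factors from matched models), per-sample paired
   t tests with tmax/tmin permutation control of the family-wise error rate,
   and a Block × Contingency stability ANOVA with Greenhouse–Geisser
   correction.

`alphasupp` implements this chain as composable, tested R functions, plus a
synthetic-data module that simulates epoched 64-channel EEG with the
paradigm's statistical structure (occipitally focal alpha with a
conditionable ERD, 1/f background noise, per-subject variability, realistic
retained-trial counts), so the whole pipeline can be exercised and validated
without any recorded data. It is aimed at EEG researchers who want a
reproducible, scriptable version of this analysis and at methodologists who
want to probe its error rates and recovery properties on simulated cohorts.

## Worked example

A desk-scale end-to-end run: six simulated subjects, the default conditioned
suppression (CS+ amplitude depth 0.5 vs. CS− 0.2 after 500 ms), wavelet grid
restricted to the alpha band.

```r
library(alphasupp)

cfg <- read_pipeline_config(
  system.file("extdata", "demo-config.yaml", package = "alphasupp"))
res <- run_pipeline(cfg)
print(res)
```

```
Occipital alpha suppression analysis report
reference: csd
config hash: 367b1bf47ba94916593d90fa9bdc6b9b; master seed: 7
subjects: 6

2x2 within-subject ANOVA (Contingency x Extinction):
Contingency: F(1, 5) = 10.64, p = 0.0224, eta_p^2 = 0.680
Extinction: F(1, 5) = 0.20, p = 0.677, eta_p^2 = 0.038
Contingency:Extinction: F(1, 5) = 0.00, p = 0.982, eta_p^2 = 0.000

Bayesian model comparison vs. null (subject-only) model:
  C: BF10 = 29.7 (MC error of log BF: 0.0227)
  E: BF10 = 1 / 2.51 (MC error of log BF: 0.0246)
  C+E: BF10 = 12.3 (MC error of log BF: 0.0253)
  C+E+CxE: BF10 = 5.89 (MC error of log BF: 0.0281)
Inclusion Bayes factors (matched models):
  Contingency: BF_Incl = 30
  Extinction: BF_Incl = 1 / 2.42
  Contingency:Extinction: BF_Incl = 1 / 2.09

Permutation test (500 permutations): t_crit -6.46 / 6.46
  significant window: 1016 to 1220 ms
  significant window: 1486 to 1706 ms

Block analysis window: 1486 to 1706 ms (permutation)
  Contingency: F(1.00, 5.00) = 26.20, GG eps = 1.000, p(GG) = 0.00371
  ...
```

Reading the output: the simulated CS+ > CS− suppression contrast is
recovered by the frequentist ANOVA (significant Contingency main effect,
no Extinction effect or interaction — the generator gave the E and N
variants identical depths), the Bayesian comparison favours the
Contingency-only model, and the permutation stage localizes the effect to
post-onset windows. At six subjects and 500 permutations the critical
values (±6.46) are far wider than a single-test t — the price of testing
1300 samples with family-wise control at this sample size.

Results are tibbles underneath: `res$effect_table` holds one row per
subject × design cell, `tidy(res$anova)`, `tidy(res$bayes)`,
`tidy(res$perm)` and `tidy(res$block)` give broom-style frames,
`autoplot(res$perm)`, `plot_alpha_cells(res$effect_table)` and
`plot_timecourses(res$timecourses, res$perm$windows)` give ggplots.
`run_pipeline(cfg, out_dir = "out")` additionally writes CSV/JSON results,
a text report and a stage log, all stamped with the config hash and seeds.
A thin command-line wrapper lives at
`system.file("scripts", "alphasupp-cli.R", package = "alphasupp")` with
`simulate`, `analyze`, `full` and `report` subcommands.

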