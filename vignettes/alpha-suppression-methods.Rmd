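---
title: "Methods: conditioned alpha suppression from epoched EEG to inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditioned alpha suppression from epoched EEG to inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alphasupp)
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic data, the analysis chain and its
assumptions, the parameters that matter, and the numerical and design
choices made where the method leaves room.

## The paradigm and the data model

The package targets two-day differential conditioning designs with four
conditioned stimuli crossing **Contingency** (CS+ paired with an aversive
noise burst during acquisition vs. CS− never paired) and **Extinction
status** (E = presented during Day-1 extinction, N = not). The analysis
concerns the Day-2 recall test: 60 presentations per CS, no reinforcement.
Epochs span −600…2000 ms around CS onset at 500 Hz — 1300 samples with the
start included and the end point excluded (`epoch_n_samples()`); per-sample
analyses therefore run exactly 1300 tests. After artifact rejection,
realistic retained-trial counts per CS lie in the 16–57 range, and the
generator draws them uniformly from that range by default.

An `epoch_array` is channels × time × trials with a montage of unit-sphere
electrode positions. The packaged 64-channel montage holds standard 10-10
positions projected to the unit sphere; the occipital region of interest is
Oz, POz, O1, O2.

## The synthetic generator

`simulate_subject()` builds each trial as

* **1/f background noise**: white noise spectrally shaped to 1/f power,
  generated per channel/trial and mixed across channels with a Gaussian
  angular kernel (width 0.35 rad) as a stand-in for volume conduction. The
  exact spatial correlation structure of real EEG is not modelled; the
  kernel width is a free parameter.
* **An occipital alpha oscillator** (10 Hz, random phase per trial) whose
  topography falls off as a Gaussian in angular distance from Oz (SD
  0.6 rad). The paradigm's occipital focality motivates the centre; the
  falloff width is a modelling choice, not an estimated quantity.
* **Event-related desynchronization** as a multiplicative amplitude
  envelope: 1 before 500 ms, a 200 ms linear ramp down to `1 − depth`,
  constant after. Real ERD has no sharp generative onset; the published
  effect window is a property of the measured response, so onset and ramp
  are explicit parameters.
* **A per-channel DC offset** (SD 20 µV), included deliberately so that the
  pipeline exercises the reference-invariance of the surface Laplacian and
  the baseline subtraction.

Per subject, the baseline alpha amplitude is drawn from N(20, 5) (nominal
µV — the absolute scale cancels in percent change) and a single shared
jitter N(0, 0.08) is added to all four suppression depths, so that
condition differences are preserved exactly within subject; in particular a
null configuration (equal depths) stays exactly null. Cohort seeds are
`master + subject index`, so any subject can be regenerated alone.

**Default depths** are CS+ 0.5 and CS− 0.2 (both extinction variants
identical). These are chosen to give desk-scale simulations a clearly
recoverable effect — a per-subject contrast whose sign is almost always
negative — rather than to match the modest effect size of the original
sample at N = 87; with realistic between-subject noise a published-scale
effect would need cohort sizes far beyond what a test suite should
simulate. The depth map is a first-class parameter for users who want to
calibrate differently.

`simulate_timecourse_cohort()` generates data one level up: per-subject
CS+/CS− alpha-percent-change timecourses as temporally correlated noise
(Gaussian smoothing with SD 191 ms, matching the 10 Hz wavelet's σ_t =
12/(2π·10)), with an optional injected difference confined to an effect
window. With no effect the two conditions are exchangeable within subject —
exactly the invariance the sign-flip permutation test assumes — which makes
it the right generator for family-wise-error studies at realistic sample
autocorrelation, where full EEG synthesis would add nothing but runtime.

## Surface Laplacian

`csd_basis()` builds the spherical-spline kernels

$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m}}P_n(x),
\qquad
h(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m-1}}P_n(x)$$

over electrode cosines, with defaults m = 4, N = 10, λ = 1e−5. Design
choices worth stating:

* **"Legendre polynomial: 10" is read as the maximum series degree** N = 10,
  matching the convention of the commercial tool this parameterization comes
  from. N is exposed, so the N = 50 convention common in research code is
  available.
* **Constant term and zero-sum constraint** are handled by the augmented
  linear system `[G + λI, 1; 1ᵀ, 0]`, the standard CSD formulation; λ is
  added to the diagonal of G only. A mean-subtraction alternative was
  rejected for numerical clarity. Because the commercial tool's exact λ
  placement is unpublished, equivalence to it is approximate by
  construction.
* **Sign convention**: the output is `H c / r²`, the *negative* surface
  Laplacian of the interpolated potential (CSD-positive = source). Tests
  assert spherical-harmonic patterns up to this documented sign.
* `head_radius` defaults to 1 (unitless output) because every downstream
  quantity is percent change, where the scale cancels.

The transform is precomputed as a single channels × channels matrix, so the
per-sample cost is one matrix product. Coincident electrodes make the
system singular and are rejected with the offending pairs named. Validated
invariants: zero output for spatially constant input, invariance to
per-time-point constant offsets (reference freedom), linearity, channel-
permutation equivariance, and ≥ 0.95 pattern correlation with the analytic
−l(l+1)·Y_lm surface Laplacian of degree-3 spherical harmonics on the
64-channel montage (λ = 0 for that check, since regularization deliberately
biases the interpolant).

## Time–frequency analysis

Epochs are baseline-corrected in the time domain (mean of −600…−500 ms
subtracted) and tapered with cosine-square flanks of 20 samples (40 ms at
500 Hz; the first and last samples become exactly 0). Complex Morlet
wavelets with m_w = f/σ_f = 12 are applied on a 3.8…30.4 Hz grid in 0.38 Hz
steps; power is the squared magnitude, averaged over trials *within*
condition, and then rescaled per frequency and channel to
`100·(P/P_base − 1)` with P_base the mean over −400…−200 ms.

Numerical and design choices:

* **Wavelet support** is truncated at ±3.5 σ_t and normalized to unit
  discrete energy, so white noise yields equal expected power in every bin.
  Convolution is FFT-based with zero padding, processed in column chunks to
  bound memory.
* **Edge handling.** Samples whose convolution window crosses the epoch
  boundary are flagged per frequency in the `edge` matrix. They are *not*
  excluded: at 10 Hz the half-support is ≈ 0.67 s, so a strict exclusion
  rule would void the −400…−200 ms baseline itself on the canonical epoch.
  Instead, selections touching flagged samples warn. The consequence —
  baseline power is somewhat attenuated by edge decay, scaling all
  percent-change values of a condition by a common factor — affects both
  conditions identically and cancels in the contrasts the method cares
  about; the normalization identity tests therefore run on longer epochs
  where the baseline is edge-clean.
* **Baseline divisor domain.** The percent-change divisor is the mean
  baseline *power* (consistent with percent-change power maps); the
  amplitude-domain reading (divide the square-rooted power) is available as
  `mode = "amplitude"` in `baseline_normalize()`, since the verbal
  description of this step is ambiguous between the two.
* **Order of operations is pinned**: average single-trial power within
  condition, then normalize with the baseline of that same average. A test
  verifies the pipeline equals normalize(mean power), not mean(normalize).
* **Band selection** snaps each endpoint of the requested band to the
  nearest grid bin within half a step and takes all bins between,
  inclusive. The conventional 8.1–11.9 Hz alpha band does not lie exactly
  on the 3.8 + k·0.38 grid; snapping selects the 11 bins 7.98…11.78 Hz,
  which is the only self-consistent reading of a "discrete frequencies from
  8.1 to 11.9 Hz" specification on that grid. Time windows use inclusive
  endpoints; the 500–1200 ms analysis window covers exactly 351 samples at
  500 Hz.

Summaries: `alpha_summary()` averages normalized power over band × ROI ×
window into one value per subject and design cell (the *effect table*);
`timecourse_summary()` keeps the full 1300-sample axis per contingency
level, averaging the two extinction variants of each level — the input to
the permutation stage.

## Frequentist and Bayesian inference

`rm_anova_2x2()` computes the within-subject ANOVA from its definitional
sums of squares: each effect tested against its own effect × subject
interaction, F = MS_effect/MS_(effect×subject) with df (1, n−1), partial
η² = SS_effect/(SS_effect + SS_error). Degenerate all-equal inputs return
F = 0 rather than 0/0. Agreement with both a longhand SS decomposition and
`stats::aov`'s multistratum fit is enforced to 1e−8 across random tables.

`bayes_model_comparison()` compares Contingency-only, Extinction-only,
additive, and full models against a subject-only null under the standard
Bayesian ANOVA model family: standardized fixed effects with Cauchy scale
0.5, subject random effects with scale 1, Jeffreys prior on the error
variance, flat prior on the grand mean. Because the design is balanced and
complete, the subject and effect subspaces are mutually orthogonal and the
marginal likelihood *given* the g parameters reduces to a closed form in
the five sums of squares; only the g's are integrated, by seeded Monte
Carlo over their InvGamma(1/2, r²/2) priors with common random numbers
across models. The Monte-Carlo standard error of each log BF is reported.
This is the same model family as the standard Bayesian ANOVA software but
an independent integrator, so numerical parity with published BF values is
approximate by construction. Inclusion Bayes factors follow the
matched-models rule — for Contingency, models {C, C+E} against {null, E};
for the interaction, full against additive — computed exactly from the
model BFs under equal prior model probabilities, and reported as "1 / x"
when below 1.

`distribution_check()` screens each cell's subject distribution with sample
skewness and excess kurtosis against the conventional |skew| ≤ 2,
|kurtosis| ≤ 7 cutoffs; constant cells yield flagged NaN rather than an
error. `within_subject_sem()` uses subject-centred values with the Morey
bias correction √(k/(k−1)), k = 4 — the error-bar variant adopted here
since within-subject SEM is not uniquely defined; it is invariant to
per-subject constants by construction.

## Permutation testing

The contingency contrast is tested at each of the 1300 samples with a
paired t statistic. Family-wise error is controlled with the tmax/tmin
approach: the CS+/CS− labels are randomly exchanged within each subject —
for a paired design this is exactly an independent sign flip of each
subject's difference series — 1000 times; each permutation's extreme t
values across samples enter tmin/tmax null distributions whose 2.5th and
97.5th percentiles become the two-sided critical values. Implementation
choices:

* Sign flips leave each subject's squared values unchanged, so all
  permutations share the per-sample sums of squares and the whole null
  computes as one matrix product — a 1000-permutation run on 24 × 1300 data
  takes well under a second.
* **Percentiles use linear interpolation** between order statistics
  (`quantile` type 7), documented because the convention shifts critical
  values by a few hundredths of a t unit.
* **The observed labeling is not forced into the null** by default; whether
  the original analysis included it is unknowable from its description, so
  `include_identity = TRUE` is available. Empirically (3000 null cohorts)
  the default procedure's family-wise error is ≈ 0.045–0.05 at the nominal
  0.05.
* Zero-variance samples yield non-finite t values that are flagged,
  excluded from the extrema with a warning, and never silently crash.
* Significant windows are maximal contiguous runs of exceedances, reported
  in ms with inclusive endpoints.

`exhaustive_signflip_oracle()` enumerates all 2ⁿ sign patterns (n ≤ 20) and
anchors the Monte-Carlo null in tests: KS distance and tail-percentile
agreement are checked at n = 12 with 100 000 permutations, where the
Monte-Carlo error of an interpolated tail quantile is safely below the
0.05 t-unit band used for the comparison.

## Block-stability analysis

Retained trials per CS are split sequentially into four blocks, remainders
to the earliest blocks (all blocks within one trial of each other). Block
condition averages are normalized per block, summarized over the
permutation-derived window (falling back to the a priori 500–1200 ms
window, with a note, if no sample is significant), and the two extinction
variants averaged. The Block × Contingency repeated-measures ANOVA uses
orthonormal within-subject contrasts; Greenhouse–Geisser ε is Box's
estimate from the contrast covariance, applied to Block-containing terms
(a 2-level factor has ε = 1 identically). The design is balanced, so
type III and type I sums of squares coincide. Follow-up per-block paired t
tests are two-sided and deliberately uncorrected, matching the descriptive
role they play. A subject with fewer than four trials in a cell is a hard
error naming the subject.

## Pipeline, seeds, and outputs

`run_pipeline()` chains generate (or load) → taper/baseline → CSD (bypass
with `no_csd = TRUE` to analyse average-referenced scalp data) → wavelet →
normalize → summaries → ANOVA/Bayes → permutation → block analysis. Named
stage seeds (`sim_seed`, `perm_seed`, `bayes_seed`) derive from one master
seed by fixed offsets; two runs of one config are byte-identical. Outputs
(CSV, JSON, text report, stage log) embed the config hash and the seeds. A
stage failure aborts with the stage named and partial outputs removed. By
default wavelet power is computed at the ROI channels only — all the
downstream summaries need — with `tf_channels = NULL` keeping full-scalp
maps for topographic work at ~16× the cost.

## Problem sizes used by the test suite

The suite validates properties at sizes chosen for a single CPU: schedule
and montage checks at full scale; ANOVA/Bayes simulations with 5–24
subjects; family-wise error on 400 null cohorts of 24 subjects × 1300
samples × 1000 permutations; full-pipeline recovery on 50 five-subject and
20 eight-subject cohorts of 64-channel EEG with 6–9 retained trials per CS
and an alpha-band-restricted wavelet grid. The acceptance script estimates
the family-wise error rate on 1000 null cohorts. These sizes are the
package's choices for informative-yet-tractable checks; every generator
parameter scales up.

## Known limitations

* The synthetic EEG is stationary 1/f noise plus a single sinusoidal
  oscillator: no spindles, no eye/muscle artifacts, no non-stationary
  background, no realistic coherence structure. Passing recovery tests
  demonstrates the pipeline's correctness and calibration under the stated
  model, not performance on arbitrary real recordings.
* The spherical-spline Laplacian assumes a spherical head and idealized
  positions; no realistic-geometry (BEM/FEM) variant is provided, and bad-
  channel interpolation is out of scope (inputs are assumed clean).
* Bayesian results carry Monte-Carlo error (reported); at very small
  iteration counts BF estimates for near-tied models can reorder.
* Phase-based measures (ITC), multitaper/STFT alternatives, cluster-mass or
  TFCE permutation variants, and frequency-dimension permutation are out of
  scope.
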