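---
title: "Trial-level neural consistency of reward responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-level neural consistency of reward responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardrsa)
```

## The question the package addresses

How *consistent* is a person's multivoxel brain response each time they
receive a reward? Representational similarity (RS) operationalises this as
the mean Pearson correlation between single-trial activation patterns of
one condition: a subject whose reward response re-instantiates the same
voxel pattern trial after trial has high RS, one whose responses wander has
low RS. In studies of adolescent anorexia nervosa (AN), reduced consistency
of reward responses — particularly after neutral (non-anxiety) contexts —
is the group difference of interest, with pubertal development (PDS, range
5–20) as the developmental covariate.

`rewardrsa` implements the whole analysis chain on synthetic data: task and
acquisition simulation with a *controllable* ground-truth consistency,
volume censoring, single-trial GLMs, RS statistics (mask-level, searchlight
and cross-condition), group inference (ANCOVA, leave-one-ROI-out MANOVA,
permutation + TFCE + FWE), and clinical association models (mixed models,
partial correlations, BH-FDR). Because the generator's reliability
parameter is known, every estimator can be validated against the truth it
is supposed to recover.

## The generative model of trial patterns

The central design choice is the reliability model. For one condition of
one subject, trial $i$'s multivoxel amplitude pattern over ROI voxels is

$$p_i = \sqrt{\rho}\,c + \sqrt{1-\rho}\,\varepsilon_i,$$

with $c$ a condition template fixed within subject and
$\varepsilon_i$ fresh standard-normal noise per trial. All components have
equal variance, so the expected trial-pair correlation is exactly $\rho$ —
RS recovery can be tested without simulation-calibrated constants. We chose
this shared-plus-idiosyncratic form over amplitude-scaling alternatives
precisely because it makes $E[r] = \rho$ analytic.

Cross-condition consistency is induced at the template level: the two
rewarded-condition templates of a subject correlate at $\kappa$, giving an
expected cross-condition pattern correlation of
$\kappa\sqrt{\rho_A \rho_B}$ — the closed form the cross-condition RS tests
check.

Patterns are convolved with a canonical double-gamma HRF (gamma shapes 6
and 16, unit dispersions, undershoot ratio 1/6, peak near 5 s, unit peak
height) and added to a baseline of 1000 intensity units inside a run of
AR(1) voxel noise (autocorrelation 0.3, a typical value at short TR).
Fractal and word phases get their own fixed-pattern nuisance responses so
that single-trial estimation must actually separate phases. Motion is
emulated only in the form DVARS can see: designated volumes receive a
global intensity jump (default four noise SDs).

What the phantom does *not* emulate: hemodynamic nonlinearity,
physiological noise, susceptibility dropout, realistic motion (rotations
and interpolation artifacts), registration error. Passing tests therefore
demonstrate the correctness of the statistical machinery and estimator
calibration under the stated model — not robustness to every property of
real data.

## Task and acquisition structure

Each session presents 60 trials of one word type (anxiety or neutral):
fractal cue 2000 ms, jittered ISI, word 2000 ms, 250 ms ISI, feedback,
jittered ISI. Rewards are i.i.d. Bernoulli(0.5), independent of everything
else. Runs are 487 volumes at TR 1000 ms.

Two timing parameters needed decisions:

* **Feedback duration** is not pinned down by the emulated protocol; we
  default to 1000 ms and expose it in `session_config()`.
* **Jitter packing.** Jitters are drawn uniformly from
  {1250, 1500, …, 2500} ms. Sixty trials with two *mean* jitters each would
  need ~540 s, which cannot fit a 487 s run, so after drawing, the largest
  jitters are decremented in 250 ms steps (deterministically, largest
  first) until the design fits. Every jitter stays inside the stated set
  and the full design remains seed-reproducible; the realised mean jitter
  is ~1.43 s. We deliberately did not re-implement design-efficiency
  optimisation: RS statistics do not depend on optimal jitter schedules.

The word-rating module mirrors stimulus selection: the 20 highest-rated
words of the group-relevant anxiety category and the 20 lowest-rated
neutral words, with rating ties at the cut-off resolved toward the best
syllable-count match (exhaustively when feasible, by deterministic greedy
swaps otherwise).

## Censoring and single-trial estimation

DVARS is the root-mean-square volume-to-volume intensity change within a
mask, after rescaling the run to a median intensity of 1000 (one fixed
normalisation rather than a tool-specific dialect; it makes the metric
invariant to global scaling). Volumes exceeding the boxplot threshold
(75th percentile + 1.5 IQR of the run's values) are censored by row
deletion — equivalent to spike regressors for OLS point estimates and
simpler to reason about.

Single-trial betas use the least-squares-sum (LSS) scheme: per trial, one
HRF-convolved regressor for the target feedback event, one for the *sum*
of all other feedback events, summed nuisance regressors for the fractal
and word phases, a cosine high-pass basis (100 s cutoff, configurable,
standing in for unspecified temporal filtering) and an intercept. Useful
exact facts, all tested: with non-overlapping responses LSS recovers
noiseless amplitudes exactly (including distinct amplitudes in the other
trials); with overlap it stays exact when the other trials share an
amplitude, while a naive target-only model is visibly biased; with trials
separated far beyond the kernel length it converges to single-trial OLS.
Registration to a common space is an identity for phantoms; GLS
(autocorrelation-whitened) estimation is out of scope.

## RS statistics

* `similarity_matrix()` — the $N \times N$ Pearson matrix across voxels
  (zero-variance trials excluded with a warning).
* `mean_pairwise_rs()` — the mean of the $N(N-1)/2$ strictly-lower-triangle
  entries; each unordered pair once, never the diagonal.
* `fisher_z()` — atanh with clipping at $|r| = 1 - 10^{-7}$ so degenerate
  noiseless fixtures stay finite.
* `searchlight_rs()` — 2-voxel-radius spheres (33 voxels in the interior)
  intersected with the mask; boundary spheres keep their in-mask voxels,
  and only pathological spheres below 5 voxels yield `NA`.
* `cross_condition_rs()` — mean Fisher-z over all $N_A \times N_B$
  cross-pairs of two conditions on the same voxel basis.

Aggregating "RS values" over a mask is genuinely ambiguous: one can
z-transform searchlight *voxel* values and average, or build one
similarity matrix from all mask voxels and average z-transformed *pairs*.
Both are implemented in `mask_rs_summary()` and the output records its
`mode`; the searchlight-voxel mode is the default, and the two are never
silently mixed. On simulated cohorts they rank subjects nearly identically
(Spearman ≥ 0.9 in the tests).

Group ANCOVAs run on log-transformed mean-z values (a skew correction).
The log is undefined for non-positive values, so `log_transform_rs()`
applies a cohort-wide shift of $-\min + 0.01$ only when needed and records
it in an attribute; requesting the log of non-positive values with shifting
disabled is an explicit error.

## Group inference

`ancova_group()` fits `value ~ covariate + group` and reports the
covariate-adjusted group F with $\eta^2 = SS_{group}/SS_{total}$ (partial
$\eta^2$ alongside). `leave_one_roi_out_manova()` repeats the multivariate
analogue with each ROI omitted, summarising the group effect by Wilks'
$\Lambda$ from explicit SSCP matrices; for a one-df contrast the F
transformation is exact, and with a single retained ROI the result reduces
to the univariate ANCOVA (tested both against matrix-algebra oracles and
`stats::anova.mlm`).

Voxelwise inference uses permutation with threshold-free cluster
enhancement. TFCE integrates $e(h)^E h^H\,dh$ over cluster-forming
thresholds; exponents are the method's standard $E = 0.5$, $H = 2$ with
$dh = \max/100$ and 26-connectivity (all configurable and recorded in the
result). The kernel is a C++ union-find sweep over descending thresholds.
Nuisance covariates are handled by the Freedman–Lane scheme (residualise
on the reduced model, permute residual rows, add the reduced fit back); a
plain label-permutation variant is available for comparison. Two-tailed
inference runs separate positive/negative TFCE passes with Bonferroni over
the tails. Family-wise error correction uses the max-statistic null with
the observed statistic included, so FWE p-values never fall below
$1/(n_{perm}+1)$. One-sample (within-group) maps mean-center the covariate
— the intercept is then the covariate-adjusted mean — and sign-flip the
covariate residuals. When the permutation space is smaller than the
requested count it is enumerated exactly with a warning. The default
permutation count is 5000; the test suite uses 500, at which the null
family-wise rejection rate over 100 simulated cohorts stays inside
[2%, 11%] at $\alpha = 0.05$.

`solve_detectable_f()` inverts fixed-effects F-test power by bisection on
the noncentral-F survival function with $\lambda = f^2 N$; at
$N = 47$, two groups, one covariate, $\alpha = 0.05$ and power 0.80 it
returns $f \approx 0.42$ — the design's medium-to-large detectable effect.

## Clinical associations

`fit_lmm()` provides three REML presets on the AN group's longitudinal
data: adjusted-BMI percentile (entry + 6 monthly visits) with a
time × cross-condition-RS interaction and random intercept + slope with
unconstrained covariance; EDE (entry/6 months); BAS (entry/6 months,
no interaction, neutral-reward RS). "Unstructured covariance for random
effects" is interpreted as the unconstrained 2×2 intercept/slope
covariance where estimable; with only two timepoints a random slope is not
identifiable, so those presets reduce to a random intercept and the
reduction is messaged and flagged rather than silent. PDS enters all three
presets identically. Boundary (singular) variance fits are reported as
converged; only genuine optimizer failures clear the flag.

`partial_corr()` residualises both variables on the covariate
(rank-transforming first for Spearman, a common convention) and correlates
the residuals, with p from the t transform on $n - 3$ df. The BH-FDR
family is always an explicit input — for the baseline severity screen it
is the three whole-sample tests run together — never inferred from
whatever happens to be in a table.

## Numerical and implementation choices

* Fisher clipping $\varepsilon = 10^{-7}$; minimum searchlight occupancy 5
  voxels; TFCE step $dh = \max/100$ unless fixed.
* 0-based voxel and volume indices everywhere; onsets in seconds from the
  first volume; column-major linear voxel order shared by masks, stacks
  and maps.
* Rank-deficient LSS designs (e.g. a target trial fully censored) raise
  errors naming the offending columns; estimation propagates them with the
  trial identity.
* All stochastic stages take explicit seeds; for a fixed seed the entire
  cohort file tree is bit-reproducible (tested by hashing).

## Problem sizes

The generator's scientific defaults are the emulated study conditions:
25 AN + 22 control subjects, two sessions each, 60 trials per session, 487
volumes at TR 1 s, and a lower neutral-reward reliability in the AN group
(0.25 vs 0.40 mean, between-subject SD 0.08) with all other conditions
matched. The package's own demonstration and test sizes are smaller by
choice — 9–12-voxel grids, 8–15 subjects, 100–500 permutations — sized so
the full pipeline demo completes in minutes on a single core; the
statistical machinery is size-agnostic.

## Known limitations

Beyond the phantom simplifications above: no motion parameter estimation
or realignment, no slice-timing correction, no random-field-theory
alternative to permutation, no exchangeability blocks beyond the whole
cohort, no dropout/missing-visit modelling in the clinical stage, and the
fractal identity carries no signal (it is treated as pure nuisance). The
zero-inflated structure of anxiety ratings in neutral runs is outside the
package's scope.
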