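# rewardrsa

Trial-level neural consistency analysis of reward responses in task fMRI,
with a fully synthetic test bed.

## The problem

In reward studies of adolescent anorexia nervosa, the question is not only
*how strongly* reward circuitry responds, but *how consistently*: does the
multivoxel activation pattern evoked by receiving a reward re-instantiate
itself trial after trial? Representational similarity (RS) indexes this as
the mean Pearson correlation between single-trial beta patterns of one
condition,

    RS = mean over trial pairs (i < j) of  r(beta_i, beta_j),

Fisher-z transformed and averaged over a reward-region mask, giving one
consistency value per subject per condition. Group differences are tested
with ANCOVA (group factor, pubertal-development score as covariate),
spatial localisation uses a 2-voxel-radius searchlight with permutation
inference (threshold-free cluster enhancement, family-wise error
correction by the max-statistic null), and associations with clinical
course use linear mixed models and covariate-adjusted partial correlations
with Benjamini–Hochberg FDR.

The package is aimed at researchers who want to run, test or extend this
pipeline without access to restricted patient data: a synthetic-cohort
module generates event designs, labelled reward-ROI phantoms and 4D BOLD
runs whose trial-to-trial pattern reliability ρ is a *known, controllable*
parameter (patterns follow `p_i = sqrt(ρ) c + sqrt(1-ρ) ε_i`, so the
expected trial-pair correlation is exactly ρ), plus participant and
longitudinal clinical tables. Every estimator in the chain is validated
against that generative truth.

## What's in the box

| stage | functions |
|---|---|
| cohort simulation | `make_word_pool()`, `select_stimuli()`, `generate_session_design()`, `build_phantom()`, `simulate_session_bold()`, `generate_cohort()` |
| QC + single-trial GLM | `compute_dvars()`, `flag_outlier_volumes()`, `censor_report()`, `hrf_kernel()`, `build_lss_design()`, `estimate_trial_betas()` |
| RS statistics | `similarity_matrix()`, `mean_pairwise_rs()`, `fisher_z()`, `sphere_offsets()`, `searchlight_rs()`, `mask_rs_summary()`, `cross_condition_rs()` |
| group inference | `ancova_group()`, `leave_one_roi_out_manova()`, `tfce()`, `permutation_group_test()`, `one_sample_perm_test()`, `solve_detectable_f()`, `f_test_power()` |
| clinical associations | `fit_lmm()` (three presets), `partial_corr()`, `bh_fdr()` |
| orchestration | `default_config()`, `validate_config()`, `run_full_pipeline()` |

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` is provided for similarity matrices and
searchlight maps.

## Worked example

One subject, one neutral-word session on a small phantom: simulate,
censor, estimate single-trial betas, summarise reward-trial consistency.

```r
library(rewardrsa)

phantom <- build_phantom(default_phantom_spec(c(12L, 12L, 12L)))
cfg     <- session_config(n_volumes = 200L, n_trials = 16L)
truth   <- subject_truth(group = "AN", pds = 14,
                         reliability = c(rewarded = 0.6, nonrewarded = 0.3),
                         noise_sd = 1, spike_volumes = c(60L, 121L))

design <- generate_session_design("neutral", seed = 7, cfg = cfg)
run    <- simulate_session_bold(design, phantom, truth, seed = 8)

censored <- flag_outlier_volumes(compute_dvars(run))
censor_report(censored, design$n_volumes, run_id = "sub-001_neutral")
#> # A tibble: 1 × 4
#>   run_id          n_excluded n_volumes pct_excluded
#>   <chr>                <int>     <int>        <dbl>
#> 1 sub-001_neutral          4       200            2

mask  <- union_mask(phantom)
stack <- estimate_trial_betas(run, mask = mask, censor = censored,
                              subject_id = "sub-001")
stack
#> <trial_beta_stack> 16 trials x 53 voxels (sub-001)

rewarded <- select_trials(stack, rewarded = TRUE)
mask_rs_summary(searchlight_rs(rewarded, mask, radius = 2), mask,
                subject_id = "sub-001", condition = "neutral_rewarded")
#> # A tibble: 1 × 6
#>   subject_id condition        mode        mean_r mean_z log_value
#>   <chr>      <chr>            <chr>        <dbl>  <dbl>     <dbl>
#> 1 sub-001    neutral_rewarded searchlight  0.559  0.678    -0.388
```

The two injected spike volumes are caught by the DVARS censor (4 volumes
flagged including the return jumps, 2% of the run), and the searchlight
mean correlation of 0.56 recovers the generative rewarded-condition
reliability of 0.6 up to estimation noise from a 16-trial session.

Design-level quantities come out of the same package:

```r
solve_detectable_f(power_query(alpha = 0.05, power = 0.80, n_total = 47))
#> [1] 0.4178468        # the N = 47 ANCOVA detects medium-to-large f ≈ 0.42

bh_fdr(c(0.028, 0.098, 0.345))
#> [1] 0.084 0.147 0.345
```

`run_full_pipeline(default_config())` chains everything — cohort
simulation, censoring, LSS betas, RS summaries, per-condition ANCOVAs,
leave-one-ROI-out MANOVA, clinical mixed models and FDR-adjusted partial
correlations — and returns the report tables with a reproducibility
manifest.

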