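mask3 <- array(TRUE, dim = c(1L, 1L, 3L))

test_that("the other-trials column is dropped for a single-event run", {
  d <- manual_design(feedback_onsets = 20, n_volumes = 80L)
  X <- build_lss_design(d, target_trial = 0, hp_cutoff = Inf)
  expect_false("others" %in% X$roles)
  expect_true(all(c("target", "intercept") %in% X$roles))
})

test_that("widely separated trials give disjoint target/other support", {
  d <- manual_design(feedback_onsets = c(10, 100), n_volumes = 200L)
  X <- build_lss_design(d, target_trial = 0, hp_cutoff = Inf)
  tgt <- X$X[, X$roles == "target"]
  oth <- X$X[, X$roles == "others"]
  expect_equal(sum(abs(tgt) > 1e-12 & abs(oth) > 1e-12), 0L)
})

test_that("censoring the whole target support is a rank error", {
  d <- manual_design(feedback_onsets = c(10, 100), n_volumes = 200L)
  expect_error(build_lss_design(d, target_trial = 0, censor = 0:60,
                                hp_cutoff = Inf),
               "rank|support")
})

test_that("noiseless non-overlapping amplitudes are recovered exactly", {
  d <- manual_design(feedback_onsets = c(10, 60, 110, 160), n_volumes = 220L)
  amps <- matrix(c(1, 2, 3,
                   -1, 0.5, 2,
                   4, -2, 1,
                   0.5, 1.5, -3), nrow = 4, byrow = TRUE)
  run <- synth_run_from_amplitudes(d, mask3, amps)
  stack <- estimate_trial_betas(run, mask = mask3, design = d,
                                hp_cutoff = Inf)
  expect_equal(stack$betas, amps, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("LSS handles overlap where a naive per-trial model fails", {
  # overlapping responses (6 s apart, 32 s kernel); all non-target trials
  # share one amplitude so the summed-others column is correctly specified
  ons <- seq(10, 46, by = 6)
  d <- manual_design(feedback_onsets = ons, n_volumes = 120L)
  amps <- matrix(rep(2, length(ons) * 3), ncol = 3)
  amps[3, ] <- c(5, -1, 3)  # distinct target amplitude
  run <- synth_run_from_amplitudes(d, mask3, amps)
  stack <- estimate_trial_betas(run, mask = mask3, design = d, trials = 2L,
                                hp_cutoff = Inf)
  expect_equal(stack$betas[1, ], amps[3, ], tolerance = 1e-8)

  # naive oracle: target regressor + intercept only, no others column
  lin <- which(mask3)
  Y <- t(matrix(run, ncol = 120L)[lin, , drop = FALSE])
  tgt <- convolve_events(ons[3], 1, 120L, 1)
  naive <- qr.coef(qr(cbind(tgt, 1)), Y)[1, ]
  expect_gt(max(abs(naive - amps[3, ])), 0.1)
})

test_that("far-separated trials reduce LSS to single-trial OLS", {
  # separation (1000 s) is far beyond twice the kernel length (32 s), and
  # the long run makes the intercept coupling between trials negligible
  d <- manual_design(feedback_onsets = c(200, 1200, 2200), n_volumes = 2600L)
  withr::with_seed(44, amps <- matrix(rnorm(9), 3))
  run <- synth_run_from_amplitudes(d, mask3, amps)
  stack <- estimate_trial_betas(run, mask = mask3, design = d,
                                hp_cutoff = Inf)
  lin <- which(mask3)
  Y <- t(matrix(run, ncol = 2600L)[lin, , drop = FALSE])
  for (tr in 1:3) {
    u <- convolve_events(d$events$onset[tr], 1, 2600L, 1)
    single <- qr.coef(qr(cbind(u, 1)), Y)[1, ]
    expect_equal(stack$betas[tr, ], unname(single), tolerance = 0.02)
  }
})

test_that("OLS residuals are orthogonal to every design column", {
  d <- manual_design(feedback_onsets = c(10, 40, 70), n_volumes = 140L)
  withr::with_seed(45, {
    amps <- matrix(rnorm(9), 3)
    run <- synth_run_from_amplitudes(d, mask3, amps)
    run <- run + array(rnorm(length(run)), dim = dim(run))
  })
  X <- build_lss_design(d, target_trial = 1)
  lin <- which(mask3)
  Y <- t(matrix(run, ncol = 140L)[lin, , drop = FALSE])[X$kept_volumes + 1L, ]
  B <- qr.coef(qr(X$X), Y)
  R <- Y - X$X %*% B
  expect_lt(max(abs(crossprod(X$X, R))), 1e-8)
})

test_that("betas are invariant to a constant intensity shift", {
  d <- manual_design(feedback_onsets = c(10, 50), n_volumes = 110L)
  withr::with_seed(46, amps <- matrix(rnorm(6), 2))
  run <- synth_run_from_amplitudes(d, mask3, amps)
  s1 <- estimate_trial_betas(run, mask = mask3, design = d)
  s2 <- estimate_trial_betas(run + 250, mask = mask3, design = d)
  expect_equal(s1$betas, s2$betas, tolerance = 1e-9)
})

test_that("censoring volumes outside all event supports leaves betas unchanged", {
  d <- manual_design(feedback_onsets = c(10, 50), n_volumes = 140L)
  withr::with_seed(47, amps <- matrix(rnorm(6), 2))
  run <- synth_run_from_amplitudes(d, mask3, amps)
  s1 <- estimate_trial_betas(run, mask = mask3, design = d, hp_cutoff = Inf)
  s2 <- estimate_trial_betas(run, mask = mask3, design = d, hp_cutoff = Inf,
                             censor = 130:139)  # long after every response
  expect_equal(s1$betas, s2$betas, tolerance = 1e-9)
})

test_that("estimated pattern correlations converge to rho at low noise", {
  ph <- small_phantom(c(8L, 8L, 8L))
  st <- subject_truth(reliability = c(rewarded = 0.6, nonrewarded = 0.6),
                      noise_sd = 0)
  d <- generate_session_design("neutral", seed = 50,
                               cfg = small_session_cfg(10L, 140L))
  run <- simulate_session_bold(d, ph, st, seed = 51)
  stack <- estimate_trial_betas(run, mask = union_mask(ph), hp_cutoff = Inf)
  est <- mean_pairwise_rs(similarity_matrix(stack$betas))
  truth <- mean_pairwise_rs(similarity_matrix(rbind(
    run$truth$patterns$neutral_rewarded$amplitudes,
    run$truth$patterns$neutral_nonrewarded$amplitudes)[order(c(
      run$truth$patterns$neutral_rewarded$trial_index,
      run$truth$patterns$neutral_nonrewarded$trial_index)) , ]))
  expect_equal(est, truth, tolerance = 0.05)
})
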