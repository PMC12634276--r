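# shared fixtures: everything generated in code, sized for fast runs

# short session that fits comfortably in a small run
small_session_cfg <- function(n_trials = 12L, n_volumes = 150L) {
  session_config(n_volumes = n_volumes, n_trials = n_trials)
}

small_phantom <- function(grid = c(10L, 10L, 10L)) {
  build_phantom(default_phantom_spec(grid))
}

# trial patterns from the shared-plus-idiosyncratic reliability model
gen_patterns <- function(n_trials, n_vox, rho, template = NULL) {
  c_vec <- if (is.null(template)) rnorm(n_vox) else template
  t(vapply(seq_len(n_trials), function(i) {
    sqrt(rho) * c_vec + sqrt(1 - rho) * rnorm(n_vox)
  }, numeric(n_vox)))
}

# wrap a patterns matrix as a trial_beta_stack on a mask
make_stack <- function(patterns, mask, rewarded = TRUE, word_type = "neutral") {
  n <- nrow(patterns)
  structure(list(
    betas = patterns,
    trials = tibble::tibble(trial_index = 0:(n - 1L),
                            word_type = word_type,
                            rewarded = rep_len(rewarded, n)),
    voxels = rewardrsa:::mask_coords(mask),
    grid_shape = dim(mask),
    subject_id = "sub-test", censor = integer(0)
  ), class = "trial_beta_stack")
}

# a hand-built design: one feedback event per row of `onsets`, optional
# fractal/word nuisance events, for LSS unit tests
manual_design <- function(feedback_onsets, feedback_dur = 1, n_volumes = 200L,
                          tr = 1, rewarded = TRUE, extra_events = NULL) {
  n <- length(feedback_onsets)
  ev <- tibble::tibble(
    onset = feedback_onsets, duration = feedback_dur, phase = "feedback",
    trial_index = 0:(n - 1L), word_type = "neutral",
    rewarded = rep_len(rewarded, n))
  if (!is.null(extra_events)) ev <- dplyr::bind_rows(ev, extra_events)
  structure(list(events = ev, n_trials = n, word_type = "neutral",
                 tr = tr, n_volumes = as.integer(n_volumes),
                 cfg = NULL), class = "session_design")
}

# synthesize a noiseless run from per-trial feedback amplitudes on a tiny
# grid; amplitudes: trials x voxels over `mask`
synth_run_from_amplitudes <- function(design, mask, amplitudes,
                                      baseline = 100, hrf = hrf_spec()) {
  grid <- dim(mask)
  nvol <- design$n_volumes
  lin <- which(mask)
  data <- array(baseline, dim = c(grid, nvol))
  fb <- design$events[design$events$phase == "feedback", ]
  ts <- matrix(0, nvol, length(lin))
  for (i in seq_len(nrow(fb))) {
    reg <- convolve_events(fb$onset[i], fb$duration[i], nvol, design$tr, hrf)
    ts <- ts + reg %o% amplitudes[i, ]
  }
  for (t in seq_len(nvol)) {
    slab <- data[, , , t]
    slab[lin] <- slab[lin] + ts[t, ]
    data[, , , t] <- slab
  }
  data
}
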