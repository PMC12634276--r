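#' Session / acquisition configuration
#'
#' Collects the task-timing and acquisition parameters of one scanning
#' session: a fast event-related reward task with 60 trials per session,
#' each trial consisting of a fractal cue (2000 ms), a jittered ISI, a word
#' stimulus (2000 ms), a short 250 ms ISI, reward/non-reward feedback, and a
#' closing jittered ISI. Acquisition defaults follow the emulated protocol:
#' TR 1000 ms and 487 volumes per run.
#'
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes per run.
#' @param n_trials Trials per session.
#' @param fractal_dur,word_dur,isi_pre_feedback,feedback_dur Phase durations
#'   in seconds. The feedback display duration is not part of the emulated
#'   protocol's printed timing; the default is 1 s and it is configurable.
#' @param jitter_set Discrete jitter values (seconds) for the two jittered
#'   ISIs of each trial; default 1.25--2.5 s in 0.25 s steps.
#' @param reward_prob Probability that a trial is rewarded (default 0.5).
#' @return A list of class `session_config`.
#' @export
session_config <- function(tr = 1, n_volumes = 487L, n_trials = 60L,
                           fractal_dur = 2, word_dur = 2,
                           isi_pre_feedback = 0.25, feedback_dur = 1,
                           jitter_set = seq(1.25, 2.5, by = 0.25),
                           reward_prob = 0.5) {
  stopifnot(tr > 0, n_volumes >= 1, n_trials >= 1,
            fractal_dur > 0, word_dur > 0, isi_pre_feedback > 0,
            feedback_dur > 0, length(jitter_set) >= 1, all(jitter_set > 0),
            reward_prob >= 0, reward_prob <= 1)
  structure(list(
    tr = tr, n_volumes = as.integer(n_volumes), n_trials = as.integer(n_trials),
    fractal_dur = fractal_dur, word_dur = word_dur,
    isi_pre_feedback = isi_pre_feedback, feedback_dur = feedback_dur,
    jitter_set = sort(jitter_set), reward_prob = reward_prob
  ), class = "session_config")
}

#' Generate one session's event design
#'
#' Lays out the trial timeline of a session: for each trial, fractal cue,
#' jittered ISI, word stimulus, 250 ms ISI, feedback, closing jittered ISI.
#' Rewards are i.i.d. Bernoulli draws (default probability 0.5) from the
#' seeded generator, independent of everything else. Jitters are drawn
#' uniformly from the discrete jitter set; if the drawn schedule would
#' overrun the run, the largest jitters are decremented in 0.25 s steps
#' (deterministically, largest first) until the design fits, keeping every
#' jitter inside the configured set. The whole design is reproducible for a
#' fixed seed.
#'
#' @param word_type `"anxiety"` or `"neutral"`; the session-level word
#'   condition (one word type per session).
#' @param seed Integer seed.
#' @param cfg A [session_config()].
#' @return An object of class `session_design`: a list with `events`
#'   (tibble: `onset`, `duration`, `phase`, `trial_index`, `word_type`,
#'   `rewarded`), `n_trials`, `word_type`, `tr`, `n_volumes`.
#' @export
generate_session_design <- function(word_type = c("anxiety", "neutral"),
                                    seed = 1L, cfg = session_config()) {
  word_type <- match.arg(word_type)
  stopifnot(inherits(cfg, "session_config"))
  run_len <- cfg$n_volumes * cfg$tr
  fixed_per_trial <- cfg$fractal_dur + cfg$word_dur + cfg$isi_pre_feedback + cfg$feedback_dur
  min_total <- cfg$n_trials * (fixed_per_trial + 2 * min(cfg$jitter_set))
  if (min_total > run_len) {
    stop(sprintf(paste0(
      "design cannot fit: %d trials need at least %.1f s but the run is ",
      "%.1f s; reduce n_trials or increase n_volumes"),
      cfg$n_trials, min_total, run_len))
  }

  withr::with_seed(seed, {
    rewarded <- stats::rbinom(cfg$n_trials, 1L, cfg$reward_prob) == 1L
    jit <- sample(cfg$jitter_set, 2L * cfg$n_trials, replace = TRUE)
  })
  jit <- fit_jitters(jit, budget = run_len - cfg$n_trials * fixed_per_trial,
                     step = min(diff(unique(sort(cfg$jitter_set))), 0.25),
                     jmin = min(cfg$jitter_set))

  onsets <- durations <- numeric(3L * cfg$n_trials)
  phases <- character(3L * cfg$n_trials)
  t0 <- 0
  for (i in seq_len(cfg$n_trials)) {
    j1 <- jit[2L * i - 1L]; j2 <- jit[2L * i]
    row <- 3L * (i - 1L)
    onsets[row + 1L] <- t0;                       durations[row + 1L] <- cfg$fractal_dur
    onsets[row + 2L] <- t0 + cfg$fractal_dur + j1; durations[row + 2L] <- cfg$word_dur
    onsets[row + 3L] <- onsets[row + 2L] + cfg$word_dur + cfg$isi_pre_feedback
    durations[row + 3L] <- cfg$feedback_dur
    phases[row + (1:3)] <- c("fractal", "word", "feedback")
    t0 <- onsets[row + 3L] + cfg$feedback_dur + j2
  }
  if (t0 > run_len + 1e-9) {
    stop("design overruns the run after jitter fitting; increase n_volumes or reduce n_trials")
  }

  events <- tibble::tibble(
    onset = onsets, duration = durations, phase = phases,
    trial_index = rep(0:(cfg$n_trials - 1L), each = 3L),
    word_type = word_type,
    rewarded = rep(rewarded, each = 3L)
  )
  structure(list(events = events, n_trials = cfg$n_trials, word_type = word_type,
                 tr = cfg$tr, n_volumes = cfg$n_volumes, seed = seed, cfg = cfg),
            class = "session_design")
}

# Shrink jitters (largest first, first index on ties) in `step` decrements
# until their sum fits within `budget`; all values stay >= jmin.
fit_jitters <- function(jit, budget, step, jmin) {
  guard <- 0L
  while (sum(jit) > budget + 1e-9) {
    i <- which.max(jit)
    if (jit[i] - step < jmin - 1e-9) {
      stop("design cannot fit even at minimum jitter; increase n_volumes or reduce n_trials")
    }
    jit[i] <- jit[i] - step
    guard <- guard + 1L
    if (guard > 1e6) stop("jitter fitting failed to converge")
  }
  jit
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %s words, %d trials (%d rewarded), %d volumes @ TR %.3g s\n",
              x$word_type, x$n_trials, sum(x$events$rewarded[x$events$phase == "feedback"]),
              x$n_volumes, x$tr))
  invisible(x)
}

#' Write / read a BIDS-style events table
#'
#' Events are serialised as tab-separated text with columns `onset`,
#' `duration`, `trial_type`, `trial_index`, `rewarded`; the round trip is
#' lossless for designs produced by [generate_session_design()] (onsets are
#' multiples of 0.25 s and survive decimal formatting exactly).
#'
#' @param design A `session_design` or an events tibble.
#' @param path Output TSV path.
#' @return `write_events_tsv()` returns `path` invisibly; `read_events_tsv()`
#'   returns the events tibble (columns as in `session_design$events`).
#' @export
write_events_tsv <- function(design, path) {
  ev <- if (inherits(design, "session_design")) design$events else design
  out <- tibble::tibble(
    onset = ev$onset, duration = ev$duration, trial_type = ev$phase,
    trial_index = ev$trial_index,
    word_type = ev$word_type,
    rewarded = as.integer(ev$rewarded)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    onset = ev$onset, duration = ev$duration, phase = ev$trial_type,
    trial_index = as.integer(ev$trial_index),
    word_type = ev$word_type,
    rewarded = ev$rewarded == 1L
  )
}
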