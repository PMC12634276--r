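#' Generative per-subject parameters
#'
#' Ground-truth parameters for one simulated participant. The central
#' quantity is `reliability`: the target expected trial-pair Pearson
#' correlation (rho) of multivoxel feedback patterns per condition. Patterns
#' follow an equal-variance shared-plus-idiosyncratic Gaussian model,
#' `p_i = sqrt(rho) c + sqrt(1 - rho) eps_i`, with `c` fixed per condition
#' per subject and `eps_i` fresh each trial, so that E[cor(p_i, p_j)] = rho.
#'
#' @param subject_id Character id.
#' @param group `"AN"` or `"CON"`.
#' @param pds Pubertal-development score in \[5, 20\].
#' @param reliability Named numeric vector of rho values in \[0, 1\], keyed
#'   by condition (e.g. `anxiety_rewarded`, `neutral_nonrewarded`; plain
#'   `rewarded` / `nonrewarded` keys act as a fallback for both sessions).
#' @param noise_sd Standard deviation of the additive AR(1) voxel noise.
#' @param spike_volumes Integer vector of 0-based volume indices receiving a
#'   global intensity jump (motion-spike stand-ins).
#' @return A list of class `subject_truth`.
#' @export
subject_truth <- function(subject_id = "sub-001", group = c("AN", "CON"),
                          pds = 12, reliability = c(rewarded = 0.5, nonrewarded = 0.5),
                          noise_sd = 1, spike_volumes = integer(0)) {
  group <- match.arg(group)
  stopifnot(pds >= 5, pds <= 20, all(reliability >= 0), all(reliability <= 1),
            noise_sd >= 0, !is.null(names(reliability)))
  structure(list(subject_id = subject_id, group = group, pds = pds,
                 reliability = reliability, noise_sd = noise_sd,
                 spike_volumes = as.integer(spike_volumes)),
            class = "subject_truth")
}

resolve_rho <- function(truth, word_type, cond) {
  key <- paste0(word_type, "_", cond)
  r <- truth$reliability
  if (key %in% names(r)) return(unname(r[[key]]))
  if (cond %in% names(r)) return(unname(r[[cond]]))
  stop(sprintf("no reliability entry for condition '%s'", key))
}

#' Simulate one session's 4D BOLD run
#'
#' Generates a 4D volume for a session design on a labelled phantom. Within
#' the ROI union mask, each feedback event elicits a multivoxel amplitude
#' pattern from the shared-plus-idiosyncratic reliability model (see
#' [subject_truth()]), convolved with the double-gamma HRF. Fractal and word
#' phases contribute separate fixed-pattern nuisance responses. All voxels
#' receive additive AR(1) noise, the run sits on a constant baseline
#' intensity, and any `spike_volumes` get a global intensity jump.
#'
#' @param design A [generate_session_design()] result.
#' @param phantom A [build_phantom()] result.
#' @param truth A [subject_truth()].
#' @param seed Integer seed.
#' @param templates Optional named list of per-condition template vectors
#'   (length = number of ROI voxels) overriding the seeded template draw;
#'   used to impose cross-condition/cross-session template correlation.
#' @param signal_amplitude Intensity units per unit pattern value (default 5).
#' @param baseline Baseline intensity (default 1000).
#' @param ar_phi AR(1) coefficient of the voxel noise (default 0.3).
#' @param spike_amplitude Global intensity jump of spike volumes; default
#'   `4 * noise_sd` (or 1 when noise-free).
#' @param hrf An [hrf_spec()].
#' @return A list of class `bold_run`: `data` (4D array), `tr`, `n_volumes`,
#'   `design`, and `truth` — the generative record (injected amplitude
#'   patterns per condition with trial indices, templates, ROI voxel
#'   coordinates, parameters).
#' @export
simulate_session_bold <- function(design, phantom, truth, seed = 1L,
                                  templates = NULL, signal_amplitude = 5,
                                  baseline = 1000, ar_phi = 0.3,
                                  spike_amplitude = NULL,
                                  hrf = hrf_spec()) {
  stopifnot(inherits(design, "session_design"), inherits(phantom, "phantom"),
            inherits(truth, "subject_truth"))
  if (any(truth$reliability < 0 | truth$reliability > 1)) {
    stop("reliability rho outside [0, 1]")
  }
  grid <- phantom$grid_shape
  nvol <- design$n_volumes
  mask <- union_mask(phantom)
  roi_lin <- which(mask)
  nvox <- length(roi_lin)
  if (is.null(spike_amplitude)) spike_amplitude <- if (truth$noise_sd > 0) 4 * truth$noise_sd else 1

  fb <- design$events[design$events$phase == "feedback", ]
  conds <- ifelse(fb$rewarded, "rewarded", "nonrewarded")

  withr::with_seed(seed, {
    # condition templates and per-trial patterns over ROI voxels
    patt <- list(); tmpl <- list()
    for (cond in c("rewarded", "nonrewarded")) {
      key <- paste0(design$word_type, "_", cond)
      rho <- resolve_rho(truth, design$word_type, cond)
      c_vec <- if (!is.null(templates) && key %in% names(templates)) {
        stopifnot(length(templates[[key]]) == nvox)
        templates[[key]]
      } else stats::rnorm(nvox)
      idx <- which(conds == cond)
      p <- matrix(0, nrow = length(idx), ncol = nvox)
      for (r in seq_along(idx)) {
        p[r, ] <- sqrt(rho) * c_vec + sqrt(1 - rho) * stats::rnorm(nvox)
      }
      tmpl[[key]] <- c_vec
      patt[[key]] <- list(patterns = p, trial_index = fb$trial_index[idx])
    }

    nuis_fractal <- stats::rnorm(nvox)
    nuis_word <- stats::rnorm(nvox)

    # assemble ROI time series: trials x voxels amplitudes -> time x voxels
    roi_ts <- matrix(0, nrow = nvol, ncol = nvox)
    for (key in names(patt)) {
      p <- patt[[key]]
      for (r in seq_len(nrow(p$patterns))) {
        ev <- fb[fb$trial_index == p$trial_index[r], ]
        reg <- convolve_events(ev$onset, ev$duration, nvol, design$tr, hrf)
        roi_ts <- roi_ts + reg %o% (signal_amplitude * p$patterns[r, ])
      }
    }
    for (ph in c("fractal", "word")) {
      ev <- design$events[design$events$phase == ph, ]
      reg <- convolve_events(ev$onset, ev$duration, nvol, design$tr, hrf)
      nu <- if (ph == "fractal") nuis_fractal else nuis_word
      roi_ts <- roi_ts + reg %o% (signal_amplitude * nu)
    }

    data <- array(baseline, dim = c(grid, nvol))
    nslab <- prod(grid)
    if (truth$noise_sd > 0) {
      innov_sd <- truth$noise_sd * sqrt(1 - ar_phi^2)
      noise <- matrix(stats::rnorm(nslab * nvol, sd = innov_sd), nrow = nslab)
      noise[, 1] <- stats::rnorm(nslab, sd = truth$noise_sd)
      for (t in 2:nvol) noise[, t] <- ar_phi * noise[, t - 1L] + noise[, t]
      data <- data + array(noise, dim = c(grid, nvol))
    }
    for (t in seq_len(nvol)) {
      slab <- data[, , , t]
      slab[roi_lin] <- slab[roi_lin] + roi_ts[t, ]
      data[, , , t] <- slab
    }
    for (sv in truth$spike_volumes) {
      data[, , , sv + 1L] <- data[, , , sv + 1L] + spike_amplitude
    }
  })

  truth_rec <- list(
    patterns = lapply(patt, function(p) {
      list(amplitudes = signal_amplitude * p$patterns, trial_index = p$trial_index)
    }),
    templates = tmpl,
    roi_coords = mask_coords(mask),
    reliability = truth$reliability, noise_sd = truth$noise_sd,
    spike_volumes = truth$spike_volumes, signal_amplitude = signal_amplitude,
    baseline = baseline, ar_phi = ar_phi, spike_amplitude = spike_amplitude,
    seed = seed
  )
  structure(list(data = data, tr = design$tr, n_volumes = nvol,
                 design = design, truth = truth_rec),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s grid, %d volumes @ TR %.3g s (%s words)\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr, x$design$word_type))
  invisible(x)
}
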