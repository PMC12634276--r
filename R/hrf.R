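#' Double-gamma haemodynamic response function
#'
#' Canonical double-gamma HRF: a gamma-density response peaking near 5 s
#' minus a scaled gamma-density undershoot, normalised to unit peak. The
#' kernel value at t = 0 is 0 and the kernel is truncated at `length_s`.
#'
#' @param peak_delay,undershoot_delay Gamma shape parameters of the response
#'   and undershoot components (scale fixed by the dispersions), in seconds.
#' @param peak_disp,undershoot_disp Gamma scale (dispersion) parameters.
#' @param ratio Undershoot amplitude relative to the peak (default 1/6).
#' @param length_s Kernel support in seconds.
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16,
                     peak_disp = 1, undershoot_disp = 1,
                     ratio = 1 / 6, length_s = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, ratio >= 0, length_s > 0)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s), class = "hrf_spec")
}

#' Sample the HRF kernel
#'
#' @param spec An [hrf_spec()].
#' @param tr Sampling interval in seconds.
#' @return Numeric vector of kernel values at `0, tr, 2 tr, ...` up to the
#'   kernel length, peak-normalised to 1; `times` attribute carries the grid.
#' @export
hrf_kernel <- function(spec = hrf_spec(), tr = 1) {
  stopifnot(inherits(spec, "hrf_spec"), tr > 0)
  t <- seq(0, spec$length_s, by = tr)
  h <- stats::dgamma(t, shape = spec$peak_delay, scale = spec$peak_disp) -
    spec$ratio * stats::dgamma(t, shape = spec$undershoot_delay,
                               scale = spec$undershoot_disp)
  # normalise on a fine grid so peak height is sampling-invariant
  tf <- seq(0, spec$length_s, by = 0.01)
  hf <- stats::dgamma(tf, shape = spec$peak_delay, scale = spec$peak_disp) -
    spec$ratio * stats::dgamma(tf, shape = spec$undershoot_delay,
                               scale = spec$undershoot_disp)
  h <- h / max(hf)
  attr(h, "times") <- t
  h
}

#' Convolve event onsets with the HRF
#'
#' Builds a boxcar on an oversampled grid, convolves with the double-gamma
#' kernel, and samples the result at volume acquisition times (volume k at
#' `k * tr`, 0-based).
#'
#' @param onsets,durations Event onsets and durations in seconds.
#' @param n_volumes,tr Run geometry.
#' @param spec An [hrf_spec()].
#' @param dt Oversampling interval (seconds).
#' @return Numeric vector of length `n_volumes`.
#' @export
convolve_events <- function(onsets, durations, n_volumes, tr,
                            spec = hrf_spec(), dt = 0.05) {
  stopifnot(length(onsets) == length(durations), n_volumes >= 1, tr > 0, dt > 0)
  if (length(onsets) == 0L) return(numeric(n_volumes))
  n_fine <- ceiling(n_volumes * tr / dt) + 1L
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    a <- floor(onsets[i] / dt) + 1L
    b <- min(n_fine, ceiling((onsets[i] + durations[i]) / dt))
    if (a <= n_fine) x[a:b] <- 1
  }
  k <- hrf_kernel(spec, tr = dt)
  y <- stats::convolve(x, rev(k), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- pmin(n_fine, round((0:(n_volumes - 1L)) * tr / dt) + 1L)
  y[vol_idx]
}
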