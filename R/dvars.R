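#' DVARS: volume-to-volume intensity change
#'
#' Computes the DVARS series of a run: the root-mean-square over mask voxels
#' of the intensity difference between successive volumes, after scaling the
#' run so its median in-mask intensity is 1000 (a fixed normalisation making
#' the metric invariant to global intensity scaling). The value at volume 0
#' is 0 by convention.
#'
#' @param run A `bold_run` or a 4D array.
#' @param mask Logical 3D array; defaults to all voxels.
#' @return A tibble of class `dvars_series` with columns `volume` (0-based)
#'   and `dvars`.
#' @export
compute_dvars <- function(run, mask = NULL) {
  data <- if (inherits(run, "bold_run")) run$data else run
  stopifnot(length(dim(data)) == 4L, dim(data)[4] >= 2L)
  grid <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  stopifnot(all(dim(mask) == grid))
  lin <- which(mask)
  if (length(lin) == 0L) stop("empty mask")
  nvol <- dim(data)[4]
  m <- matrix(data, ncol = nvol)[lin, , drop = FALSE]
  med <- stats::median(m)
  if (med != 0) m <- m * (1000 / med)
  d <- sqrt(colMeans((m[, -1L, drop = FALSE] - m[, -nvol, drop = FALSE])^2))
  out <- tibble::tibble(volume = 0:(nvol - 1L), dvars = c(0, d))
  class(out) <- c("dvars_series", class(out))
  out
}

#' Flag motion-outlier volumes from a DVARS series
#'
#' Applies the boxplot-style default threshold: a volume is excluded when
#' its DVARS value strictly exceeds the 75th percentile plus 1.5 times the
#' interquartile range of the run's DVARS values (quantiles with linear
#' interpolation).
#'
#' @param dvars A `dvars_series` (or tibble with `volume`, `dvars`).
#' @return Sorted integer vector of 0-based excluded volume indices, with
#'   attribute `threshold`.
#' @export
flag_outlier_volumes <- function(dvars) {
  stopifnot(is.data.frame(dvars), nrow(dvars) >= 1L,
            all(c("volume", "dvars") %in% names(dvars)))
  q <- stats::quantile(dvars$dvars, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  excluded <- sort(as.integer(dvars$volume[dvars$dvars > thr]))
  attr(excluded, "threshold") <- thr
  excluded
}

#' Censoring report
#'
#' Summarises a censor set against the run length, including the percentage
#' of excluded volumes.
#'
#' @param excluded Integer vector of 0-based excluded volume indices.
#' @param n_volumes Run length in volumes.
#' @param run_id Optional run identifier.
#' @return One-row tibble: `run_id`, `n_excluded`, `n_volumes`,
#'   `pct_excluded`.
#' @export
censor_report <- function(excluded, n_volumes, run_id = NA_character_) {
  stopifnot(n_volumes >= 1L, all(excluded >= 0L), all(excluded < n_volumes))
  tibble::tibble(
    run_id = run_id,
    n_excluded = length(excluded),
    n_volumes = as.integer(n_volumes),
    pct_excluded = 100 * length(excluded) / n_volumes
  )
}
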