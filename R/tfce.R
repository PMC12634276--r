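#' TFCE parameters
#'
#' Threshold-free cluster enhancement settings: extent exponent `E`, height
#' exponent `H`, integration step `dh` and neighbourhood connectivity.
#' Defaults are the method's standard values (E = 0.5, H = 2, dh =
#' max(map)/100, 26-connectivity).
#'
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Integration step; `NULL` means `max(map) / n_steps`.
#' @param n_steps Steps used when `dh` is `NULL`.
#' @param connectivity 6, 18 or 26.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_steps = 100L,
                        connectivity = 26L) {
  stopifnot(E > 0, H > 0, is.null(dh) || dh > 0, n_steps >= 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(E = E, H = H, dh = dh, n_steps = as.integer(n_steps),
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' For each mask voxel p, integrates extent^E x height^H over cluster-forming
#' thresholds h = dh, 2dh, ... up to the voxel's height, where the extent is
#' the size of the connected suprathreshold component containing p at h.
#' Negative map values are enhanced on the negated map separately and
#' returned with their sign, so the output is an odd function of a sign flip
#' of the input.
#'
#' @param stat_map 3D array (or numeric vector of mask-voxel values).
#' @param params A [tfce_params()].
#' @param mask Logical 3D array; required when `stat_map` is a vector.
#' @return Same shape as the input: enhanced values on the mask, `NA` (array
#'   input) outside.
#' @export
tfce <- function(stat_map, params = tfce_params(), mask = NULL) {
  stopifnot(inherits(params, "tfce_params"))
  vector_in <- is.null(dim(stat_map))
  if (vector_in) {
    stopifnot(!is.null(mask))
    vals <- as.numeric(stat_map)
    coords <- mask_coords(mask)
  } else {
    if (is.null(mask)) mask <- array(TRUE, dim = dim(stat_map))
    vals <- stat_map[which(mask)]
    coords <- mask_coords(mask)
  }
  stopifnot(length(vals) == nrow(coords), all(is.finite(vals)))
  dims <- as.integer(dim(mask))
  dh <- if (is.null(params$dh)) -1 else params$dh

  enh <- tfce_masked(vals, coords, dims, params, dh)
  if (vector_in) return(enh)
  out <- array(NA_real_, dim = dims)
  out[which(mask)] <- enh
  class(out) <- c("tfce_map", "array")
  out
}

tfce_masked <- function(vals, coords, dims, params, dh) {
  pos <- pmax(vals, 0)
  neg <- pmax(-vals, 0)
  enh <- numeric(length(vals))
  if (any(pos > 0)) {
    enh <- enh + .tfce_cpp(pos, coords, dims, params$E, params$H, dh,
                           params$n_steps, params$connectivity)
  }
  if (any(neg > 0)) {
    enh <- enh - .tfce_cpp(neg, coords, dims, params$E, params$H, dh,
                           params$n_steps, params$connectivity)
  }
  enh
}
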