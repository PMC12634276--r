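#' Trial-by-trial similarity matrix
#'
#' Pearson-correlates every pair of trial patterns across voxels, giving the
#' N x N similarity matrix whose off-diagonal summarises trial-to-trial
#' neural consistency. Trials with zero-variance patterns are excluded with
#' a warning.
#'
#' @param patterns Trials x voxels numeric matrix, or a `trial_beta_stack`.
#' @param condition Optional condition label stored on the result.
#' @return A matrix of class `similarity_matrix` (symmetric, unit diagonal)
#'   with attributes `condition` and `trial_index`.
#' @export
similarity_matrix <- function(patterns, condition = NULL) {
  trial_index <- NULL
  if (inherits(patterns, "trial_beta_stack")) {
    trial_index <- patterns$trials$trial_index
    patterns <- patterns$betas
  }
  stopifnot(is.matrix(patterns), nrow(patterns) >= 2L, ncol(patterns) >= 3L)
  sds <- apply(patterns, 1, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  if (any(bad)) {
    warning(sprintf("excluding %d zero-variance trial pattern(s): %s",
                    sum(bad), paste(which(bad), collapse = ", ")))
    patterns <- patterns[!bad, , drop = FALSE]
    if (!is.null(trial_index)) trial_index <- trial_index[!bad]
    if (nrow(patterns) < 2L) stop("fewer than 2 usable trial patterns")
  }
  m <- stats::cor(t(patterns))
  diag(m) <- 1
  structure(m, class = c("similarity_matrix", "matrix"),
            condition = condition, trial_index = trial_index)
}

#' Mean pairwise representational similarity
#'
#' Average of the N(N-1)/2 strictly-lower-triangle entries of a similarity
#' matrix — each unordered trial pair counted once, diagonal never included.
#'
#' @param simmat A `similarity_matrix` (or plain symmetric matrix).
#' @return Scalar mean correlation.
#' @export
mean_pairwise_rs <- function(simmat) {
  stopifnot(is.matrix(simmat), nrow(simmat) >= 2L)
  mean(simmat[lower.tri(simmat)])
}

#' Fisher r-to-z transform
#'
#' Variance-stabilising `atanh` with clipping at 1 - 1e-7 in absolute value
#' so degenerate (|r| = 1) inputs map to large finite values.
#'
#' @param r Correlations in \[-1, 1\].
#' @return z values.
#' @export
fisher_z <- function(r) {
  stopifnot(all(is.na(r) | (r >= -1 & r <= 1)))
  eps <- 1e-7
  atanh(pmin(1 - eps, pmax(-1 + eps, r)))
}

#' Integer sphere offsets
#'
#' All integer offset triples within Euclidean distance `radius` of the
#' origin; a 2-voxel radius yields 33 offsets, matching the searchlight
#' sphere size.
#'
#' @param radius Nonnegative radius in voxel units.
#' @return Integer matrix (n x 3) of offsets, containing `(0,0,0)`.
#' @export
sphere_offsets <- function(radius = 2) {
  stopifnot(radius >= 0)
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  out <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Searchlight map of trial-to-trial consistency
#'
#' Slides a 2-voxel-radius sphere over every mask voxel; the map value at a
#' voxel is the mean pairwise trial correlation computed over the sphere's
#' voxels (sphere intersected with the mask — boundary spheres keep their
#' in-mask voxels). Spheres below `min_voxels` yield `NA`.
#'
#' @param stack A `trial_beta_stack` (optionally pre-filtered), or a trials
#'   x voxels matrix whose columns correspond to `mask` voxels in linear
#'   order.
#' @param mask Logical 3D array.
#' @param radius Sphere radius in voxel units (default 2).
#' @param rewarded,word_type Optional trial filters (see [select_trials()]).
#' @param min_voxels Minimum sphere occupancy (default 5).
#' @return A 3D array of class `searchlight_map` (`NA` outside the mask)
#'   with attributes `mask`, `radius`, `n_trials`.
#' @export
searchlight_rs <- function(stack, mask, radius = 2, rewarded = NULL,
                           word_type = NULL, min_voxels = 5L) {
  if (inherits(stack, "trial_beta_stack")) {
    stack <- select_trials(stack, rewarded = rewarded, word_type = word_type)
    patterns <- stack$betas
  } else {
    patterns <- stack
  }
  stopifnot(length(dim(mask)) == 3L, is.matrix(patterns))
  lin <- which(mask)
  if (ncol(patterns) != length(lin)) {
    stop("pattern columns do not match mask voxel count")
  }
  if (nrow(patterns) < 2L) stop("condition selects fewer than 2 trials")

  grid <- dim(mask)
  col_of <- array(NA_integer_, dim = grid)
  col_of[lin] <- seq_along(lin)
  off <- sphere_offsets(radius)
  coords <- arrayInd(lin, grid)  # 1-based

  out <- array(NA_real_, dim = grid)
  for (i in seq_along(lin)) {
    nb <- sweep(off, 2L, coords[i, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= grid[1] &
      nb[, 2] >= 1L & nb[, 2] <= grid[2] &
      nb[, 3] >= 1L & nb[, 3] <= grid[3]
    nb <- nb[ok, , drop = FALSE]
    cols <- col_of[nb]
    cols <- cols[!is.na(cols)]
    if (length(cols) < min_voxels) next
    cm <- suppressWarnings(stats::cor(t(patterns[, cols, drop = FALSE])))
    out[lin[i]] <- mean(cm[lower.tri(cm)], na.rm = TRUE)
  }
  structure(out, class = c("searchlight_map", "array"), mask = mask,
            radius = radius, n_trials = nrow(patterns))
}

#' Mask-level RS summary
#'
#' Aggregates representational similarity over a region mask into one value
#' per subject and condition. Two aggregation modes are provided (and never
#' silently mixed): `"searchlight"` (default) Fisher-z transforms each
#' voxel's searchlight r and averages across mask voxels; `"pairs"` builds
#' one similarity matrix from all mask voxels and averages the z-transformed
#' trial pairs. `log_value` is the natural log of `mean_z` (for ANCOVA after
#' skew correction) and is only defined for positive `mean_z` unless a shift
#' is applied cohort-wide via [log_transform_rs()].
#'
#' @param x A `searchlight_map` (searchlight mode) or `trial_beta_stack`.
#' @param mask Logical 3D array.
#' @param mode `"searchlight"` or `"pairs"`.
#' @param subject_id,condition Metadata columns for the output row.
#' @param ... Passed to [searchlight_rs()] when a stack is supplied in
#'   searchlight mode.
#' @return One-row tibble: `subject_id`, `condition`, `mode`, `mean_r`,
#'   `mean_z`, `log_value`.
#' @export
mask_rs_summary <- function(x, mask, mode = c("searchlight", "pairs"),
                            subject_id = NA_character_,
                            condition = NA_character_, ...) {
  mode <- match.arg(mode)
  if (mode == "searchlight") {
    map <- if (inherits(x, "searchlight_map")) x else searchlight_rs(x, mask, ...)
    vals <- map[which(mask)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) stop("no defined searchlight values on mask")
    mean_r <- mean(vals)
    mean_z <- mean(fisher_z(vals))
  } else {
    stopifnot(inherits(x, "trial_beta_stack"))
    sm <- similarity_matrix(x)
    mean_r <- mean_pairwise_rs(sm)
    mean_z <- mean(fisher_z(sm[lower.tri(sm)]))
  }
  tibble::tibble(
    subject_id = subject_id, condition = condition, mode = mode,
    mean_r = mean_r, mean_z = mean_z,
    log_value = ifelse(mean_z > 0, log(mean_z), NA_real_)
  )
}

#' Log-transform a cohort of RS values
#'
#' Natural log of the per-subject mean-z RS values, applied cohort-wide: if
#' every value is positive the plain log is used; otherwise the values are
#' shifted by `-min + delta` first (recorded in the `shift` attribute). An
#' error is raised if a non-positive value occurs and shifting is disabled.
#'
#' @param values Numeric vector of mean-z RS values.
#' @param shift Allow the shift fallback (default TRUE).
#' @param delta Shift offset (default 0.01).
#' @return Log-transformed vector with attribute `shift`.
#' @export
log_transform_rs <- function(values, shift = TRUE, delta = 0.01) {
  stopifnot(is.numeric(values))
  if (all(values > 0)) {
    out <- log(values)
    attr(out, "shift") <- 0
    return(out)
  }
  if (!shift) stop("non-positive RS value with log requested and no shift configured")
  s <- -min(values) + delta
  out <- log(values + s)
  attr(out, "shift") <- s
  out
}

#' Cross-condition representational similarity
#'
#' Correlates every trial pattern of condition A with every trial pattern of
#' condition B (all N_A x N_B cross pairs), Fisher-z transforms, and
#' averages — an index of how consistent reward representations are across
#' the two word contexts (higher = more similar across contexts).
#'
#' @param patterns_a,patterns_b Trials x voxels matrices (or
#'   `trial_beta_stack`s) on the same voxel basis.
#' @return One-row tibble: `n_a`, `n_b`, `mean_r`, `mean_z`.
#' @export
cross_condition_rs <- function(patterns_a, patterns_b) {
  va <- vb <- NULL
  if (inherits(patterns_a, "trial_beta_stack")) {
    va <- patterns_a$voxels; patterns_a <- patterns_a$betas
  }
  if (inherits(patterns_b, "trial_beta_stack")) {
    vb <- patterns_b$voxels; patterns_b <- patterns_b$betas
  }
  stopifnot(is.matrix(patterns_a), is.matrix(patterns_b),
            nrow(patterns_a) >= 1L, nrow(patterns_b) >= 1L)
  if (ncol(patterns_a) != ncol(patterns_b)) {
    stop("voxel-basis mismatch between the two pattern sets")
  }
  if (!is.null(va) && !is.null(vb) && !identical(va, vb)) {
    stop("voxel-basis mismatch between the two pattern sets")
  }
  cc <- stats::cor(t(patterns_a), t(patterns_b))
  z <- fisher_z(cc)
  tibble::tibble(n_a = nrow(patterns_a), n_b = nrow(patterns_b),
                 mean_r = mean(cc), mean_z = mean(z))
}
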