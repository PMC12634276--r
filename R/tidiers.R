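#' Tidy a similarity matrix into trial pairs
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per unordered trial pair: `trial_i`,
#'   `trial_j`, `r`, `z`.
#' @exportS3Method generics::tidy
tidy.similarity_matrix <- function(x, ...) {
  n <- nrow(x)
  idx <- which(lower.tri(x), arr.ind = TRUE)
  ti <- attr(x, "trial_index") %||% (seq_len(n) - 1L)
  tibble::tibble(trial_i = ti[idx[, 2]], trial_j = ti[idx[, 1]],
                 r = x[idx], z = fisher_z(x[idx]))
}

#' Tidy a permutation-test result into voxels
#'
#' @param x A `perm_result`.
#' @param ... Unused.
#' @return Tibble with one row per analysed voxel: 0-based `x`, `y`, `z`
#'   coordinates, `stat`, `tfce`, `fwe_p`.
#' @exportS3Method generics::tidy
tidy.perm_result <- function(x, ...) {
  lin <- which(!is.na(x$fwe_p_map))
  co <- arrayInd(lin, dim(x$fwe_p_map)) - 1L
  stat <- x$stat_map[lin]; tfce <- x$tfce_map[lin]; fwe <- x$fwe_p_map[lin]
  tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                 stat = stat, tfce = tfce, fwe_p = fwe)
}

#' @rdname tidy.perm_result
#' @exportS3Method generics::glance
glance.perm_result <- function(x, ...) {
  tibble::tibble(n_voxels = sum(!is.na(x$fwe_p_map)),
                 n_perm = x$n_perm,
                 min_fwe_p = min(x$fwe_p_map, na.rm = TRUE),
                 n_sig_05 = sum(x$fwe_p_map < 0.05, na.rm = TRUE),
                 method = x$method, seed = x$seed)
}

#' Tidy / glance methods for mixed-model results
#'
#' @param x An `lmm_result` from [fit_lmm()].
#' @param ... Unused.
#' @return `tidy()`: the fixed-effects table; `glance()`: one-row fit
#'   summary (REML criterion, convergence, random structure).
#' @exportS3Method generics::tidy
tidy.lmm_result <- function(x, ...) x$fixed

#' @rdname tidy.lmm_result
#' @exportS3Method generics::glance
glance.lmm_result <- function(x, ...) {
  tibble::tibble(
    reml = as.numeric(stats::REMLcrit(x$fit)),
    aic = stats::AIC(x$fit),
    n_obs = stats::nobs(x$fit),
    converged = x$converged,
    reduced_random = x$reduced_random
  )
}
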