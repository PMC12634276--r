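#' Stack of per-subject maps
#'
#' Bundles one map per subject (e.g. searchlight z maps) with the analysis
#' mask for voxelwise group inference. Voxels that are undefined (`NA`) for
#' any subject are excluded from the analysis mask.
#'
#' @param maps A list of 3D arrays (one per subject) or an n_subjects x
#'   n_mask_voxels matrix in the mask's linear voxel order.
#' @param mask Logical 3D array.
#' @param subject_ids Optional ids.
#' @return A list of class `map_stack`: `values` (subjects x voxels),
#'   `mask` (analysis mask after NA exclusion), `coords`, `subject_ids`.
#' @export
map_stack <- function(maps, mask, subject_ids = NULL) {
  stopifnot(length(dim(mask)) == 3L)
  lin <- which(mask)
  if (is.list(maps)) {
    values <- do.call(rbind, lapply(maps, function(m) {
      stopifnot(all(dim(m)[1:3] == dim(mask)))
      as.numeric(m)[lin]
    }))
  } else {
    values <- as.matrix(maps)
    stopifnot(ncol(values) == length(lin))
  }
  ok <- colSums(!is.finite(values)) == 0L
  mask2 <- array(FALSE, dim = dim(mask))
  mask2[lin[ok]] <- TRUE
  structure(list(values = values[, ok, drop = FALSE], mask = mask2,
                 coords = mask_coords(mask2),
                 subject_ids = subject_ids %||%
                   sprintf("sub-%03d", seq_len(nrow(values)))),
            class = "map_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# voxelwise t statistics for one column of a fixed design
t_map_ols <- function(Y, X, col) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  R <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(R^2) / df
  se <- sqrt(pmax(s2 * XtXi[col, col], .Machine$double.eps))
  as.numeric(B[col, ] / se)
}

perm_fwe_p <- function(obs, null_max, n_perm) {
  vapply(obs, function(v) (1 + sum(null_max >= v - 1e-12)) / (n_perm + 1),
         numeric(1))
}

#' Permutation test of a group difference on voxel maps
#'
#' Voxelwise two-sample comparison adjusted for a nuisance covariate,
#' with TFCE enhancement and max-statistic family-wise error correction.
#' The observed statistic is the group-coefficient t map from the model
#' `map ~ 1 + covariate + group`. The null distribution uses the
#' Freedman-Lane scheme by default: maps are residualised on the reduced
#' (covariate-only) model, residual rows are permuted, the reduced fit is
#' added back, and the full model is refit; each permuted t map is TFCE
#' enhanced and its maximum retained. Two-tailed inference runs separate
#' positive/negative TFCE passes with Bonferroni correction over the two
#' tails.
#'
#' @param stack A [map_stack()].
#' @param group Factor/character of length n_subjects with two levels.
#' @param covariate Numeric nuisance covariate.
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed.
#' @param params A [tfce_params()].
#' @param method `"freedman_lane"` (default) or `"simple"` (plain label
#'   permutation ignoring the covariate).
#' @param two_tailed Bonferroni over the two TFCE tails (default TRUE).
#' @return A list of class `perm_result`: `stat_map`, `tfce_map`,
#'   `fwe_p_map` (3D arrays), `n_perm`, `seed`, `params`, `method`,
#'   `two_tailed`, `mask`.
#' @export
permutation_group_test <- function(stack, group, covariate, n_perm = 5000L,
                                   seed = 1L, params = tfce_params(),
                                   method = c("freedman_lane", "simple"),
                                   two_tailed = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "map_stack"))
  Y <- stack$values
  n <- nrow(Y)
  g <- factor(group)
  stopifnot(length(g) == n, length(covariate) == n, nlevels(g) == 2L,
            all(table(g) >= 2L))
  gi <- as.numeric(g) - 1
  X <- cbind(intercept = 1, covariate = covariate, group = gi)
  dims <- as.integer(dim(stack$mask))
  dh <- if (is.null(params$dh)) -1 else params$dh

  t_obs <- t_map_ols(Y, X, 3L)
  enhance <- function(tv) {
    list(pos = .tfce_cpp(pmax(tv, 0), stack$coords, dims, params$E, params$H,
                         dh, params$n_steps, params$connectivity),
         neg = .tfce_cpp(pmax(-tv, 0), stack$coords, dims, params$E, params$H,
                         dh, params$n_steps, params$connectivity))
  }
  obs <- enhance(t_obs)

  # distinct label assignments for the simple scheme; FL permutes residual
  # rows so its space is n! and practically never exhausted
  n1 <- sum(gi == 1)
  if (method == "simple" && choose(n, n1) <= n_perm) {
    warning(sprintf("n_perm (%d) meets or exceeds the %d distinct label assignments; enumerating exactly",
                    n_perm, choose(n, n1)))
    assign_idx <- utils::combn(n, n1)
    perms <- lapply(seq_len(ncol(assign_idx)), function(k) assign_idx[, k])
    n_perm <- length(perms)
  } else {
    perms <- NULL
  }

  Xr <- X[, 1:2, drop = FALSE]
  fit_r <- Xr %*% (solve(crossprod(Xr)) %*% crossprod(Xr, Y))
  res_r <- Y - fit_r

  max_pos <- max_neg <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (method == "freedman_lane") {
        pr <- sample.int(n)
        tb <- t_map_ols(fit_r + res_r[pr, , drop = FALSE], X, 3L)
      } else {
        gp <- numeric(n)
        gp[if (is.null(perms)) sample.int(n, n1) else perms[[b]]] <- 1
        Xp <- X; Xp[, 3] <- gp
        tb <- t_map_ols(Y, Xp, 3L)
      }
      eb <- enhance(tb)
      max_pos[b] <- max(eb$pos); max_neg[b] <- max(eb$neg)
    }
  })

  p_pos <- perm_fwe_p(obs$pos, max_pos, n_perm)
  p_neg <- perm_fwe_p(obs$neg, max_neg, n_perm)
  fwe <- if (two_tailed) pmin(1, 2 * pmin(p_pos, p_neg)) else p_pos

  as_map <- function(v) {
    out <- array(NA_real_, dim = dims); out[which(stack$mask)] <- v; out
  }
  structure(list(stat_map = as_map(t_obs),
                 tfce_map = as_map(obs$pos - obs$neg),
                 fwe_p_map = as_map(fwe),
                 n_perm = n_perm, seed = seed, params = params,
                 method = method, two_tailed = two_tailed,
                 mask = stack$mask),
            class = "perm_result")
}

#' One-sample permutation test on voxel maps
#'
#' Tests whether the within-group mean map differs from zero, adjusting for
#' a mean-centered covariate (`map ~ 1 + centered covariate`; the intercept
#' is the covariate-adjusted group mean). The null distribution sign-flips
#' the covariate-residualised maps, with TFCE and max-statistic FWE
#' correction as in [permutation_group_test()].
#'
#' @inheritParams permutation_group_test
#' @return A `perm_result`.
#' @export
one_sample_perm_test <- function(stack, covariate, n_perm = 5000L, seed = 1L,
                                 params = tfce_params(), two_tailed = TRUE) {
  stopifnot(inherits(stack, "map_stack"))
  Y <- stack$values
  n <- nrow(Y)
  stopifnot(length(covariate) == n, n >= 3L)
  zc <- covariate - mean(covariate)
  X <- cbind(intercept = 1, covariate = zc)
  dims <- as.integer(dim(stack$mask))
  dh <- if (is.null(params$dh)) -1 else params$dh

  t_obs <- t_map_ols(Y, X, 1L)
  enhance <- function(tv) {
    list(pos = .tfce_cpp(pmax(tv, 0), stack$coords, dims, params$E, params$H,
                         dh, params$n_steps, params$connectivity),
         neg = .tfce_cpp(pmax(-tv, 0), stack$coords, dims, params$E, params$H,
                         dh, params$n_steps, params$connectivity))
  }
  obs <- enhance(t_obs)

  flips <- NULL
  if (2^n <= n_perm) {
    warning(sprintf("n_perm (%d) meets or exceeds the %d distinct sign flips; enumerating exactly",
                    n_perm, 2^n))
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(flips)
  }

  # reduced model for the intercept test: covariate only (no intercept)
  Xr <- X[, 2, drop = FALSE]
  fit_r <- Xr %*% (solve(crossprod(Xr)) %*% crossprod(Xr, Y))
  res_r <- Y - fit_r

  max_pos <- max_neg <- numeric(n_perm)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      s <- if (is.null(flips)) sample(c(-1, 1), n, replace = TRUE) else flips[b, ]
      tb <- t_map_ols(fit_r + s * res_r, X, 1L)
      eb <- enhance(tb)
      max_pos[b] <- max(eb$pos); max_neg[b] <- max(eb$neg)
    }
  })

  p_pos <- perm_fwe_p(obs$pos, max_pos, n_perm)
  p_neg <- perm_fwe_p(obs$neg, max_neg, n_perm)
  fwe <- if (two_tailed) pmin(1, 2 * pmin(p_pos, p_neg)) else p_pos

  as_map <- function(v) {
    out <- array(NA_real_, dim = dims); out[which(stack$mask)] <- v; out
  }
  structure(list(stat_map = as_map(t_obs),
                 tfce_map = as_map(obs$pos - obs$neg),
                 fwe_p_map = as_map(fwe),
                 n_perm = n_perm, seed = seed, params = params,
                 method = "sign_flip", two_tailed = two_tailed,
                 mask = stack$mask),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  nv <- sum(!is.na(x$fwe_p_map))
  cat(sprintf("<perm_result> %s, %d permutations, %d voxels, %d voxels FWE p < 0.05\n",
              x$method, x$n_perm, nv, sum(x$fwe_p_map < 0.05, na.rm = TRUE)))
  invisible(x)
}
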