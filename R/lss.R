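#' Build a least-squares-sum (LSS) design matrix for one trial
#'
#' Constructs the per-trial GLM of the LSS scheme: one HRF-convolved
#' regressor for the target trial's feedback event, one for the sum of all
#' other feedback events, nuisance regressors for the fractal and word
#' phases (one summed regressor each), a cosine high-pass drift basis and an
#' intercept. Rows of censored volumes are deleted.
#'
#' @param design A `session_design`.
#' @param target_trial 0-based trial index whose feedback event is the
#'   target.
#' @param censor Integer vector of 0-based volume indices to drop.
#' @param hrf An [hrf_spec()].
#' @param hp_cutoff High-pass cutoff in seconds for the cosine drift basis
#'   (default 100 s); `Inf` disables drift columns.
#' @return A list of class `lss_design`: `X` (uncensored-volumes x
#'   regressors), `roles` (column roles), `kept_volumes` (0-based).
#' @export
build_lss_design <- function(design, target_trial, censor = integer(0),
                             hrf = hrf_spec(), hp_cutoff = 100) {
  stopifnot(inherits(design, "session_design"))
  fb <- design$events[design$events$phase == "feedback", ]
  if (!target_trial %in% fb$trial_index) {
    stop(sprintf("target_trial %d has no feedback event in this design", target_trial))
  }
  nvol <- design$n_volumes; tr <- design$tr

  tgt <- fb[fb$trial_index == target_trial, ]
  oth <- fb[fb$trial_index != target_trial, ]
  cols <- list(target = convolve_events(tgt$onset, tgt$duration, nvol, tr, hrf))
  if (nrow(oth) > 0L) {
    cols$others <- convolve_events(oth$onset, oth$duration, nvol, tr, hrf)
  }
  for (ph in c("fractal", "word")) {
    ev <- design$events[design$events$phase == ph, ]
    if (nrow(ev) > 0L) {
      cols[[ph]] <- convolve_events(ev$onset, ev$duration, nvol, tr, hrf)
    }
  }
  if (is.finite(hp_cutoff)) {
    run_len <- nvol * tr
    K <- floor(2 * run_len / hp_cutoff)
    if (K >= 1L) {
      t_idx <- 0:(nvol - 1L)
      for (k in seq_len(K)) {
        cols[[paste0("drift", k)]] <- cos(pi * k * (t_idx + 0.5) / nvol)
      }
    }
  }
  cols$intercept <- rep(1, nvol)

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  keep <- setdiff(0:(nvol - 1L), as.integer(censor))
  X <- X[keep + 1L, , drop = FALSE]

  # drop structurally empty columns (e.g. no "other" trials), then rank-check
  empty <- apply(X, 2, function(v) max(abs(v)) < 1e-12)
  offending <- colnames(X)[empty & colnames(X) != "intercept"]
  X <- X[, !(empty & colnames(X) != "intercept"), drop = FALSE]
  if (length(offending) > 0L && any(offending == "target")) {
    stop("design rank-deficient after censoring: column(s) ",
         paste(offending, collapse = ", "), " have no remaining support")
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design rank-deficient after censoring: column(s) ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, roles = colnames(X), kept_volumes = keep,
                 target_trial = target_trial), class = "lss_design")
}

#' Estimate single-trial beta patterns (LSS)
#'
#' For every feedback trial of a run, fits the trial's LSS design by
#' ordinary least squares and collects the target-trial coefficient at each
#' mask voxel, yielding a trials x voxels pattern stack with condition
#' metadata — the substrate of all representational-similarity computation.
#'
#' @param run A `bold_run` (or 4D array, in which case `design` must be
#'   given).
#' @param mask Logical 3D array restricting output voxels; default all
#'   voxels.
#' @param censor Integer vector of 0-based censored volume indices.
#' @param design A `session_design`; taken from `run` when it is a
#'   `bold_run`.
#' @param trials Optional 0-based trial indices to estimate (default all).
#' @param subject_id Carried into the stack metadata.
#' @param hrf,hp_cutoff Passed to [build_lss_design()].
#' @return A list of class `trial_beta_stack`: `betas` (trials x voxels),
#'   `trials` (tibble `trial_index`, `word_type`, `rewarded`), `voxels`
#'   (0-based n x 3 coordinate matrix), `subject_id`, `censor`.
#' @export
estimate_trial_betas <- function(run, mask = NULL, censor = integer(0),
                                 design = NULL, trials = NULL,
                                 subject_id = NA_character_,
                                 hrf = hrf_spec(), hp_cutoff = 100) {
  if (inherits(run, "bold_run")) {
    design <- run$design
    data <- run$data
  } else {
    data <- run
    if (is.null(design)) stop("design required when run is a bare array")
  }
  stopifnot(length(dim(data)) == 4L, inherits(design, "session_design"))
  grid <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = grid)
  stopifnot(all(dim(mask) == grid))
  lin <- which(mask)
  if (length(lin) == 0L) stop("empty mask")

  fb <- design$events[design$events$phase == "feedback", ]
  if (is.null(trials)) trials <- fb$trial_index

  nvol <- dim(data)[4]
  Y_full <- t(matrix(data, ncol = nvol)[lin, , drop = FALSE])  # volumes x voxels

  betas <- matrix(NA_real_, nrow = length(trials), ncol = length(lin))
  for (i in seq_along(trials)) {
    d <- tryCatch(
      build_lss_design(design, trials[i], censor = censor, hrf = hrf,
                       hp_cutoff = hp_cutoff),
      error = function(e) stop(sprintf("trial %d: %s", trials[i], conditionMessage(e)),
                               call. = FALSE))
    Y <- Y_full[d$kept_volumes + 1L, , drop = FALSE]
    coefs <- qr.coef(qr(d$X), Y)
    betas[i, ] <- coefs[which(d$roles == "target"), ]
  }

  meta <- fb[match(trials, fb$trial_index), c("trial_index", "word_type", "rewarded")]
  structure(list(betas = betas, trials = tibble::as_tibble(meta),
                 voxels = mask_coords(mask), grid_shape = grid,
                 subject_id = subject_id, censor = as.integer(censor)),
            class = "trial_beta_stack")
}

#' Subset a beta stack by condition
#'
#' @param stack A `trial_beta_stack`.
#' @param rewarded Logical filter on the reward outcome (NULL = keep all).
#' @param word_type Filter on the session word type (NULL = keep all).
#' @return A `trial_beta_stack` with the selected trials.
#' @export
select_trials <- function(stack, rewarded = NULL, word_type = NULL) {
  stopifnot(inherits(stack, "trial_beta_stack"))
  keep <- rep(TRUE, nrow(stack$trials))
  if (!is.null(rewarded)) keep <- keep & stack$trials$rewarded == rewarded
  if (!is.null(word_type)) keep <- keep & stack$trials$word_type == word_type
  stack$betas <- stack$betas[keep, , drop = FALSE]
  stack$trials <- stack$trials[keep, , drop = FALSE]
  stack
}

#' @export
print.trial_beta_stack <- function(x, ...) {
  cat(sprintf("<trial_beta_stack> %d trials x %d voxels (%s)\n",
              nrow(x$betas), ncol(x$betas),
              ifelse(is.na(x$subject_id), "unnamed subject", x$subject_id)))
  invisible(x)
}
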