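#' Default pipeline configuration
#'
#' A single-command demo profile: a reduced cohort (8 AN + 7 CON) on a
#' 12-voxel grid with the full 60-trial / 487-volume session structure, RS
#' aggregation in searchlight mode, and 500 permutations for the optional
#' voxelwise stage. All stochastic stages carry explicit seeds.
#'
#' @param seed Base seed; stage seeds are derived deterministically.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seeds = list(simulate = seed, perm = seed + 1000L),
    cohort = cohort_spec(
      n_an = 8L, n_con = 7L,
      phantom = default_phantom_spec(c(12L, 12L, 12L))
    ),
    rs = list(mode = "searchlight", radius = 2, min_voxels = 5L),
    inference = list(run_searchlight = FALSE, n_perm = 500L,
                     tfce = tfce_params(), alpha = 0.05),
    clinical = list(fdr_family = c("cdrs", "ham_a", "adjusted_bmi")),
    out_dir = NULL
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: required seeds, valid RS aggregation
#' mode, a task design that fits the run length, sane reliability values
#' and a permutation count of at least 100 when the voxelwise stage is
#' enabled.
#'
#' @param config A `run_config`.
#' @return A tibble of issues (`field`, `issue`); zero rows when valid.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(field, issue) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(field = field, issue = issue)
  }
  if (is.null(config$seeds$simulate)) add("seeds$simulate", "missing seed for the simulation stage")
  if (isTRUE(config$inference$run_searchlight) && is.null(config$seeds$perm)) {
    add("seeds$perm", "missing seed for the permutation stage")
  }
  if (!is.null(config$rs$mode) && !config$rs$mode %in% c("searchlight", "pairs")) {
    add("rs$mode", "RS aggregation mode must be 'searchlight' or 'pairs'")
  }
  cs <- config$cohort
  if (!inherits(cs, "cohort_spec")) {
    add("cohort", "not a cohort_spec")
  } else {
    cfg <- cs$session_cfg
    fixed <- cfg$n_trials * (cfg$fractal_dur + cfg$word_dur +
                               cfg$isi_pre_feedback + cfg$feedback_dur +
                               2 * min(cfg$jitter_set))
    if (fixed > cfg$n_volumes * cfg$tr) {
      add("cohort$session_cfg", sprintf(
        "designed trial time (%.1f s minimum) exceeds the run length (%.1f s)",
        fixed, cfg$n_volumes * cfg$tr))
    }
    rho <- unlist(cs$rho_mean)
    if (any(rho < 0 | rho > 1)) add("cohort$rho_mean", "reliability rho outside [0, 1]")
  }
  if (isTRUE(config$inference$run_searchlight) &&
      (is.null(config$inference$n_perm) || config$inference$n_perm < 100L)) {
    add("inference$n_perm", "at least 100 permutations required")
  }
  if (length(issues) == 0L) {
    return(tibble::tibble(field = character(), issue = character()))
  }
  dplyr::bind_rows(issues)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> censor/betas -> RS -> group inference ->
#' clinical associations on a synthetic cohort and returns a report plus a
#' reproducibility manifest. Stages:
#' \enumerate{
#'   \item simulate the cohort ([generate_cohort()]);
#'   \item per run: DVARS censoring and LSS single-trial betas on the union
#'     ROI mask;
#'   \item per subject: mask-level RS per condition (configured aggregation
#'     mode), per-ROI RS (pairs mode) for the sensitivity MANOVA, and
#'     cross-condition RS of the two rewarded conditions;
#'   \item ANCOVA (group + PDS covariate) per condition on cohort-log RS,
#'     leave-one-ROI-out MANOVA, and optionally the voxelwise searchlight
#'     permutation test;
#'   \item clinical LMM presets and covariate-adjusted partial correlations
#'     with BH-FDR over the configured family.
#' }
#'
#' @param config A `run_config` from [default_config()].
#' @return A list of class `pipeline_result` with `report` (tibbles:
#'   `rs_table`, `ancova`, `manova`, `clinical_lmm`, `partial_corr`;
#'   optionally `searchlight` perm results) and `manifest` (config hash,
#'   seeds, stage log, censoring summary).
#' @export
run_full_pipeline <- function(config = default_config()) {
  issues <- validate_config(config)
  if (nrow(issues) > 0L) {
    stop("invalid config:\n", paste0("  - ", issues$field, ": ", issues$issue,
                                     collapse = "\n"))
  }
  stage_log <- character()
  tick <- function(name) stage_log <<- c(stage_log, name)

  tick("simulate")
  cohort <- generate_cohort(config$cohort, seed = config$seeds$simulate,
                            out_dir = config$out_dir)
  phantom <- cohort$phantom
  mask <- union_mask(phantom)
  n <- nrow(cohort$participants)

  tick("qc_betas_rsa")
  mode <- config$rs$mode %||% "searchlight"
  radius <- config$rs$radius %||% 2
  rois <- phantom$legend$roi
  rs_rows <- list(); roi_rows <- list(); cross_rows <- list()
  censor_rows <- list()
  sl_maps <- list()
  for (i in seq_len(n)) {
    id <- cohort$participants$subject_id[i]
    stacks <- list()
    for (wt in c("anxiety", "neutral")) {
      run <- get_run(cohort, i, wt)
      dv <- compute_dvars(run)
      cens <- flag_outlier_volumes(dv)
      censor_rows[[paste(id, wt)]] <-
        censor_report(cens, run$design$n_volumes, run_id = paste(id, wt, sep = "_"))
      stacks[[wt]] <- estimate_trial_betas(run, mask = mask, censor = cens,
                                           subject_id = id)
    }
    for (wt in c("anxiety", "neutral")) {
      for (rw in c(TRUE, FALSE)) {
        cond <- paste0(wt, "_", ifelse(rw, "rewarded", "nonrewarded"))
        sub <- select_trials(stacks[[wt]], rewarded = rw)
        if (mode == "searchlight") {
          slm <- searchlight_rs(sub, mask, radius = radius,
                                min_voxels = config$rs$min_voxels %||% 5L)
          rs_rows[[paste(id, cond)]] <-
            mask_rs_summary(slm, mask, mode = "searchlight",
                            subject_id = id, condition = cond)
          if (cond == "neutral_rewarded") sl_maps[[id]] <- fisher_z(unclass(slm))
        } else {
          rs_rows[[paste(id, cond)]] <-
            mask_rs_summary(sub, mask, mode = "pairs",
                            subject_id = id, condition = cond)
        }
        # per-ROI RS (pairs over each region's voxels) for the MANOVA
        if (rw) {
          for (roi in rois) {
            rmask <- union_mask(phantom, roi)
            sel <- rmask[which(mask)]
            pat <- sub$betas[, sel, drop = FALSE]
            if (ncol(pat) >= 3L) {
              sm <- similarity_matrix(pat)
              roi_rows[[paste(id, cond, roi)]] <- tibble::tibble(
                subject_id = id, condition = cond, roi = roi,
                mean_z = mean(fisher_z(sm[lower.tri(sm)])))
            }
          }
        }
      }
    }
    cr <- cross_condition_rs(select_trials(stacks$anxiety, rewarded = TRUE),
                             select_trials(stacks$neutral, rewarded = TRUE))
    cross_rows[[id]] <- dplyr::mutate(cr, subject_id = id, .before = 1)
  }
  rs_table <- dplyr::bind_rows(rs_rows)
  roi_table <- dplyr::bind_rows(roi_rows)
  cross_table <- dplyr::bind_rows(cross_rows)
  censor_table <- dplyr::bind_rows(censor_rows)

  tick("group_inference")
  wide <- dplyr::left_join(
    tidyr::pivot_wider(rs_table[, c("subject_id", "condition", "mean_z")],
                       names_from = "condition", values_from = "mean_z"),
    cohort$participants, by = "subject_id")
  conds <- intersect(unique(rs_table$condition), names(wide))
  ancova_tab <- purrr::map_dfr(conds, function(cond) {
    lv <- log_transform_rs(wide[[cond]])
    d <- dplyr::mutate(wide, .log_rs = as.numeric(lv))
    res <- ancova_group(d, ".log_rs", group = "group", covariate = "pds")
    dplyr::mutate(res, condition = cond, log_shift = attr(lv, "shift"),
                  .before = 1)
  })

  roi_wide <- dplyr::left_join(
    tidyr::pivot_wider(
      roi_table[roi_table$condition == "neutral_rewarded",
                c("subject_id", "roi", "mean_z")],
      names_from = "roi", values_from = "mean_z"),
    cohort$participants, by = "subject_id")
  roi_cols <- intersect(rois, names(roi_wide))
  manova_tab <- if (length(roi_cols) >= 2L &&
                    nrow(roi_wide) > length(roi_cols) + 3L) {
    leave_one_roi_out_manova(roi_wide, roi_cols, group = "group",
                             covariate = "pds")
  } else {
    tibble::tibble()
  }

  searchlight_res <- NULL
  if (isTRUE(config$inference$run_searchlight) && mode == "searchlight") {
    stk <- map_stack(sl_maps[cohort$participants$subject_id], mask)
    searchlight_res <- permutation_group_test(
      stk, cohort$participants$group, cohort$participants$pds,
      n_perm = config$inference$n_perm, seed = config$seeds$perm,
      params = config$inference$tfce)
  }

  tick("clinical")
  rs_subject <- dplyr::left_join(
    dplyr::select(cross_table, "subject_id", rs_cross = "mean_z"),
    dplyr::select(dplyr::filter(rs_table, .data$condition == "neutral_rewarded"),
                  "subject_id", rs_neutral = "mean_z"),
    by = "subject_id")
  clin <- dplyr::left_join(cohort$clinical, rs_subject, by = "subject_id")
  clin <- dplyr::left_join(clin, cohort$participants, by = "subject_id")

  lmm_results <- list()
  an_long <- dplyr::filter(clin, .data$group == "AN")
  for (preset in c("adjusted_bmi", "ede", "bas")) {
    d <- dplyr::filter(an_long, .data$measure == preset)
    if (nrow(d) == 0L) next
    d <- tidyr::pivot_wider(d, names_from = "measure", values_from = "value")
    d$time <- timepoint_to_months(d$timepoint)
    lmm_results[[preset]] <- tryCatch(
      fit_lmm(d, preset = preset),
      error = function(e) e)
  }
  lmm_tab <- purrr::map_dfr(names(lmm_results), function(nm) {
    r <- lmm_results[[nm]]
    if (inherits(r, "error")) {
      return(tibble::tibble(model = nm, term = NA_character_,
                            estimate = NA_real_, se = NA_real_, df = NA_real_,
                            statistic = NA_real_, p = NA_real_,
                            converged = FALSE))
    }
    dplyr::mutate(r$fixed, model = nm, converged = r$converged, .before = 1)
  })

  base <- dplyr::filter(clin, .data$timepoint == "entry")
  base_wide <- tidyr::pivot_wider(
    base[, c("subject_id", "group", "pds", "rs_neutral", "measure", "value")],
    names_from = "measure", values_from = "value")
  fam <- intersect(config$clinical$fdr_family, names(base_wide))
  pc_tab <- purrr::map_dfr(fam, function(m) {
    res <- partial_corr(base_wide, "rs_neutral", m, covariate = "pds",
                        method = "spearman")
    dplyr::mutate(res, measure = m, .before = 1)
  })
  if (nrow(pc_tab) > 0L) pc_tab$p_adj <- bh_fdr(pc_tab$p)

  tick("report")
  report <- list(rs_table = rs_table, roi_table = roi_table,
                 cross_table = cross_table, censor_table = censor_table,
                 ancova = ancova_tab, manova = manova_tab,
                 searchlight = searchlight_res,
                 clinical_lmm = lmm_tab, clinical_lmm_fits = lmm_results,
                 partial_corr = pc_tab, participants = cohort$participants)
  manifest <- list(config_hash = config_hash(config),
                   seeds = config$seeds, stages = stage_log,
                   n_subjects = n,
                   grid_shape = config$cohort$phantom$grid_shape,
                   rs_mode = mode,
                   censor_summary = list(
                     mean_pct = mean(censor_table$pct_excluded),
                     max_pct = max(censor_table$pct_excluded)))
  structure(list(report = report, manifest = manifest, config = config),
            class = "pipeline_result")
}

get_run <- function(cohort, i, word_type) {
  if (!is.null(cohort$runs)) return(cohort$runs[[i]][[word_type]])
  id <- cohort$participants$subject_id[i]
  sdir <- file.path(cohort$out_dir, id, paste0("ses-", word_type))
  data <- read_nifti(file.path(sdir, "bold.nii.gz"))
  ev <- read_events_tsv(file.path(sdir, "events.tsv"))
  cfg <- cohort$spec$session_cfg
  design <- structure(list(events = ev, n_trials = cfg$n_trials,
                           word_type = word_type, tr = cfg$tr,
                           n_volumes = cfg$n_volumes, cfg = cfg),
                      class = "session_design")
  structure(list(data = data, tr = cfg$tr, n_volumes = cfg$n_volumes,
                 design = design, truth = NULL), class = "bold_run")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  strip <- rapply(unclass(config), function(x) x, how = "replace")
  jsonlite::write_json(strip, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat("  subjects:", x$manifest$n_subjects, "\n")
  if (nrow(x$report$ancova) > 0) {
    cat("  ANCOVA (log RS ~ group + pds):\n")
    print(x$report$ancova[, c("condition", "F", "df1", "df2", "p", "eta_sq")])
  }
  invisible(x)
}
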