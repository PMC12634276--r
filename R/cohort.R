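#' Cohort specification
#'
#' Generative parameters for a full synthetic cohort: group sizes (default
#' 25 AN + 22 controls), per-group-and-condition trial-pattern reliability
#' (rho), the cross-condition template correlation (kappa) linking the two
#' rewarded conditions across sessions, the pubertal-development covariate,
#' acquisition noise / motion spikes, and longitudinal clinical
#' trajectories. Defaults encode the cohort structure the package emulates:
#' a lower neutral-word rewarded-trial reliability in the AN group (the
#' group effect the inference stages are built to detect), all other
#' conditions matched across groups.
#'
#' @param n_an,n_con Group sizes.
#' @param session_cfg A [session_config()].
#' @param phantom A [phantom_spec()].
#' @param rho_mean Named list `AN` / `CON`, each a named vector of mean rho
#'   per condition (`anxiety_rewarded`, `anxiety_nonrewarded`,
#'   `neutral_rewarded`, `neutral_nonrewarded`).
#' @param rho_sd Between-subject SD of rho (truncated to \[0, 1\]).
#' @param kappa_mean,kappa_sd Cross-condition template correlation of the
#'   two rewarded conditions (truncated to \[0, 1\]).
#' @param pds_mean,pds_sd Per-group PDS distribution (truncated to
#'   \[5, 20\]); named vectors with entries `AN`, `CON`.
#' @param noise_sd AR(1) voxel noise SD.
#' @param spike_lambda Poisson mean of motion-spike volumes per run.
#' @param clinical List of trajectory parameters (see defaults in the
#'   function signature): adjusted-BMI entry/slope, the optional linear
#'   dependence of the adjusted-BMI slope on the subject's true
#'   cross-condition RS (`bmi_slope_rs_beta`), EDE and BAS entry/change,
#'   baseline CDRS and HAM-A by group.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_an = 25L, n_con = 22L,
                        session_cfg = session_config(),
                        phantom = default_phantom_spec(),
                        rho_mean = list(
                          AN = c(anxiety_rewarded = 0.40, anxiety_nonrewarded = 0.40,
                                 neutral_rewarded = 0.25, neutral_nonrewarded = 0.40),
                          CON = c(anxiety_rewarded = 0.40, anxiety_nonrewarded = 0.40,
                                  neutral_rewarded = 0.40, neutral_nonrewarded = 0.40)),
                        rho_sd = 0.08,
                        kappa_mean = 0.3, kappa_sd = 0.15,
                        pds_mean = c(AN = 15, CON = 15),
                        pds_sd = c(AN = 2.5, CON = 2.5),
                        noise_sd = 1, spike_lambda = 12,
                        clinical = list(
                          bmi_entry_mean = 15, bmi_entry_sd = 5,
                          bmi_slope_mean = 3, bmi_slope_sd = 1,
                          bmi_slope_rs_beta = 0, bmi_resid_sd = 2,
                          ede_entry_mean = 3, ede_entry_sd = 1,
                          ede_change_mean = -1, ede_change_sd = 0.8,
                          bas_entry_mean = 38, bas_entry_sd = 8,
                          bas_change_mean = 2, bas_change_sd = 4,
                          cdrs_mean = c(AN = 40, CON = 25),
                          cdrs_sd = c(AN = 10, CON = 7),
                          hama_mean = c(AN = 15, CON = 7),
                          hama_sd = c(AN = 6, CON = 4))) {
  stopifnot(n_an >= 1, n_con >= 1, inherits(session_cfg, "session_config"),
            inherits(phantom, "phantom_spec"), rho_sd >= 0)
  structure(list(n_an = as.integer(n_an), n_con = as.integer(n_con),
                 session_cfg = session_cfg, phantom = phantom,
                 rho_mean = rho_mean, rho_sd = rho_sd,
                 kappa_mean = kappa_mean, kappa_sd = kappa_sd,
                 pds_mean = pds_mean, pds_sd = pds_sd,
                 noise_sd = noise_sd, spike_lambda = spike_lambda,
                 clinical = clinical),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject generative parameters (group, PDS, per-condition rho,
#' cross-condition kappa, spike volumes), simulates two sessions per subject
#' (anxiety-word and neutral-word, each with rewarded/non-rewarded trials),
#' and builds the participants and clinical tables. With `out_dir` set, the
#' BIDS-style file tree is written
#' (`sub-XXX/ses-{anxiety,neutral}/{bold.nii.gz,events.tsv}`,
#' `participants.csv`, `clinical.csv`, `phantom.nii.gz`, `manifest.json`)
#' and image data are not retained in memory; without `out_dir` the
#' simulated runs are kept in the returned object (only sensible for small
#' grids). The whole tree is reproducible bit-for-bit for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return A list of class `cohort`: `participants` (tibble `subject_id`,
#'   `group`, `pds`), `clinical` (long tibble `subject_id`, `measure`,
#'   `timepoint`, `value`), `truth` (per-subject generative parameters),
#'   `phantom`, `spec`, `seed`, `out_dir`, and — when data are retained —
#'   `runs` (list of per-subject lists `anxiety` / `neutral` of
#'   `bold_run`s).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  phantom <- build_phantom(spec$phantom)
  nvox <- sum(phantom$labels != 0L)
  n <- spec$n_an + spec$n_con
  groups <- rep(c("AN", "CON"), c(spec$n_an, spec$n_con))
  ids <- sprintf("sub-%03d", seq_len(n))
  keep_data <- is.null(out_dir)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  conds <- c("anxiety_rewarded", "anxiety_nonrewarded",
             "neutral_rewarded", "neutral_nonrewarded")
  # per-subject parameter draws (one seeded block, order fixed)
  withr::with_seed(seed, {
    pds <- rtrunc_norm(n, spec$pds_mean[groups], spec$pds_sd[groups], 5, 20)
    kappa <- rtrunc_norm(n, spec$kappa_mean, spec$kappa_sd, 0, 1)
    rho <- t(vapply(seq_len(n), function(i) {
      mu <- spec$rho_mean[[groups[i]]][conds]
      rtrunc_norm(length(conds), mu, spec$rho_sd, 0, 1)
    }, numeric(length(conds))))
    colnames(rho) <- conds
    n_spikes <- stats::rpois(2L * n, spec$spike_lambda)
    n_spikes <- pmin(n_spikes, floor(0.13 * spec$session_cfg$n_volumes))
    subj_seeds <- sample.int(.Machine$integer.max, 4L * n)
  })

  runs <- if (keep_data) vector("list", n) else NULL
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    # correlated rewarded-condition templates across the two sessions
    tset <- withr::with_seed(subj_seeds[4L * i - 3L], {
      c1 <- stats::rnorm(nvox); c2 <- stats::rnorm(nvox)
      list(anxiety_rewarded = c1,
           neutral_rewarded = kappa[i] * c1 + sqrt(1 - kappa[i]^2) * c2)
    })
    spikes <- withr::with_seed(subj_seeds[4L * i - 2L], {
      list(anxiety = sort(sample.int(spec$session_cfg$n_volumes,
                                     n_spikes[2L * i - 1L]) - 1L),
           neutral = sort(sample.int(spec$session_cfg$n_volumes,
                                     n_spikes[2L * i]) - 1L))
    })
    subj_runs <- list()
    for (wt in c("anxiety", "neutral")) {
      st <- subject_truth(ids[i], groups[i], pds[i],
                          reliability = rho[i, ], noise_sd = spec$noise_sd,
                          spike_volumes = spikes[[wt]])
      des <- generate_session_design(wt, seed = subj_seeds[4L * i - 1L] %% 100000L + i,
                                     cfg = spec$session_cfg)
      run <- simulate_session_bold(des, phantom, st,
                                   seed = subj_seeds[4L * i] %% 100000L +
                                     i + (wt == "neutral") * 50000L,
                                   templates = tset)
      if (!is.null(out_dir)) {
        sdir <- file.path(out_dir, ids[i], paste0("ses-", wt))
        dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
        write_nifti(run$data, file.path(sdir, "bold.nii.gz"), tr = run$tr)
        write_events_tsv(des, file.path(sdir, "events.tsv"))
        run$data <- NULL
      }
      subj_runs[[wt]] <- run
    }
    if (keep_data) runs[[i]] <- subj_runs
    truth[[i]] <- list(subject_id = ids[i], group = groups[i], pds = pds[i],
                       rho = rho[i, ], kappa = kappa[i],
                       rs_cross_true = kappa[i] * sqrt(rho[i, "anxiety_rewarded"] *
                                                         rho[i, "neutral_rewarded"]),
                       spike_volumes = spikes)
  }

  participants <- tibble::tibble(subject_id = ids, group = groups, pds = pds)
  clinical <- make_clinical_table(participants, truth, spec$clinical, seed)

  out <- structure(list(participants = participants, clinical = clinical,
                        truth = truth, phantom = phantom, spec = spec,
                        seed = seed, out_dir = out_dir, runs = runs),
                   class = "cohort")
  if (!is.null(out_dir)) {
    readr::write_csv(participants, file.path(out_dir, "participants.csv"))
    readr::write_csv(clinical, file.path(out_dir, "clinical.csv"))
    write_nifti(phantom$labels, file.path(out_dir, "phantom.nii.gz"))
    manifest <- list(
      seed = seed,
      n_an = spec$n_an, n_con = spec$n_con,
      grid_shape = spec$phantom$grid_shape,
      session = spec$session_cfg[c("tr", "n_volumes", "n_trials")],
      rho_mean = spec$rho_mean, rho_sd = spec$rho_sd,
      kappa = list(mean = spec$kappa_mean, sd = spec$kappa_sd),
      noise_sd = spec$noise_sd, spike_lambda = spec$spike_lambda,
      subjects = lapply(truth, function(t) {
        t$spike_volumes <- lapply(t$spike_volumes, as.integer); t
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# longitudinal clinical trajectories (AN group) + baseline severity (all)
make_clinical_table <- function(participants, truth, cl, seed) {
  withr::with_seed(seed + 7L, {
    rows <- list()
    rs_true <- vapply(truth, function(t) t$rs_cross_true, numeric(1))
    rs_ctr <- rs_true - mean(rs_true)
    for (i in seq_len(nrow(participants))) {
      id <- participants$subject_id[i]
      grp <- participants$group[i]
      cdrs <- rtrunc_norm(1, cl$cdrs_mean[[grp]], cl$cdrs_sd[[grp]], 0, 100)
      hama <- rtrunc_norm(1, cl$hama_mean[[grp]], cl$hama_sd[[grp]], 0, 56)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = id, measure = c("cdrs", "ham_a"), timepoint = "entry",
        value = c(cdrs, hama))
      if (grp == "AN") {
        entry <- rtrunc_norm(1, cl$bmi_entry_mean, cl$bmi_entry_sd, 0, 100)
        slope <- stats::rnorm(1, cl$bmi_slope_mean + cl$bmi_slope_rs_beta * rs_ctr[i],
                              cl$bmi_slope_sd)
        months <- 0:6
        bmi <- pmin(100, pmax(0, entry + slope * months +
                                stats::rnorm(7, 0, cl$bmi_resid_sd)))
        ede0 <- max(0, stats::rnorm(1, cl$ede_entry_mean, cl$ede_entry_sd))
        ede6 <- max(0, ede0 + stats::rnorm(1, cl$ede_change_mean, cl$ede_change_sd))
        bas0 <- stats::rnorm(1, cl$bas_entry_mean, cl$bas_entry_sd)
        bas6 <- bas0 + stats::rnorm(1, cl$bas_change_mean, cl$bas_change_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = id, measure = "adjusted_bmi",
          timepoint = c("entry", paste0("month", 1:6)), value = bmi)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = id, measure = c("ede", "ede", "bas", "bas"),
          timepoint = c("entry", "month6", "entry", "month6"),
          value = c(ede0, ede6, bas0, bas6))
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = id, measure = "adjusted_bmi", timepoint = "entry",
          value = rtrunc_norm(1, 50, 25, 0, 100))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Timepoint labels as months since entry
#'
#' @param timepoint Character vector (`"entry"`, `"month1"`, ..., `"month6"`).
#' @return Numeric months.
#' @export
timepoint_to_months <- function(timepoint) {
  out <- ifelse(timepoint == "entry", 0,
                suppressWarnings(as.numeric(sub("^month", "", timepoint))))
  if (any(is.na(out))) stop("unrecognised timepoint label")
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d AN + %d CON subjects, grid %s%s\n",
              sum(x$participants$group == "AN"),
              sum(x$participants$group == "CON"),
              paste(x$spec$phantom$grid_shape, collapse = "x"),
              if (!is.null(x$out_dir)) paste0(", written to ", x$out_dir) else ""))
  invisible(x)
}
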