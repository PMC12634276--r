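#' Longitudinal linear mixed models for clinical outcomes
#'
#' REML mixed-model fits relating clinical trajectories to
#' representational-similarity measures, with the pubertal-development score
#' as a covariate. Three presets mirror the analysis plan:
#' \describe{
#'   \item{`adjusted_bmi`}{adjusted-BMI percentile over entry + 6 monthly
#'     visits, fixed effects time x cross-condition RS (interaction on) +
#'     PDS, random intercept and time slope per subject with unconstrained
#'     2 x 2 covariance.}
#'   \item{`ede`}{EDE global score at entry and 6 months, time x
#'     cross-condition RS + PDS; with two timepoints a random slope is not
#'     identifiable, so the random structure reduces to an intercept (the
#'     reduction is messaged and flagged).}
#'   \item{`bas`}{BAS score at entry and 6 months, time + neutral-reward RS
#'     + PDS (no interaction), random intercept.}
#' }
#'
#' @param data Long-format data frame with one row per subject x timepoint:
#'   columns `subject_id`, a numeric time column, the outcome, an RS column
#'   and the covariate.
#' @param outcome,time,rs,covariate Column names.
#' @param interaction Include the time x RS interaction (default TRUE).
#' @param random `"slope"` (intercept + time slope, unstructured covariance)
#'   or `"intercept"`.
#' @param preset One of `"adjusted_bmi"`, `"ede"`, `"bas"`; fills the other
#'   arguments (`outcome` defaults to the preset's standard column name and
#'   `rs` to `rs_cross` / `rs_neutral`).
#' @param subject Subject id column.
#' @return A list of class `lmm_result`: `fixed` (tibble of estimates, SEs,
#'   df, t and p per term), `ranef_cov` (random-effects covariance matrix),
#'   `converged`, `reduced_random`, `fit` (the lmerTest fit), `formula`.
#' @export
fit_lmm <- function(data, outcome = NULL, time = "time", rs = NULL,
                    covariate = "pds", interaction = TRUE,
                    random = c("slope", "intercept"),
                    preset = NULL, subject = "subject_id") {
  random <- match.arg(random)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("adjusted_bmi", "ede", "bas"))
    defs <- switch(preset,
      adjusted_bmi = list(outcome = "adjusted_bmi", rs = "rs_cross",
                          interaction = TRUE, random = "slope"),
      ede = list(outcome = "ede", rs = "rs_cross",
                 interaction = TRUE, random = "slope"),
      bas = list(outcome = "bas", rs = "rs_neutral",
                 interaction = FALSE, random = "intercept"))
    outcome <- outcome %||% defs$outcome
    rs <- rs %||% defs$rs
    interaction <- defs$interaction
    random <- defs$random
  }
  stopifnot(!is.null(outcome), !is.null(rs),
            all(c(outcome, time, rs, covariate, subject) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(outcome, time, rs, covariate, subject)]), ]
  n_tp <- length(unique(data[[time]]))
  if (n_tp < 2L) stop("need at least 2 timepoints per subject")

  reduced <- FALSE
  if (random == "slope" && n_tp < 3L) {
    message("two timepoints: random slope not identifiable; reducing random structure to intercept-only")
    random <- "intercept"
    reduced <- TRUE
  }
  fe <- if (interaction) {
    sprintf("%s * %s + %s", time, rs, covariate)
  } else {
    sprintf("%s + %s + %s", time, rs, covariate)
  }
  re <- if (random == "slope") {
    sprintf("(1 + %s | %s)", time, subject)
  } else {
    sprintf("(1 | %s)", subject)
  }
  fml <- stats::as.formula(sprintf("%s ~ %s + %s", outcome, fe, re))

  fit <- suppressMessages(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # boundary (singular) fits are legitimate for degenerate variance structure
  converged <- !any(grepl("failed to converge", msgs, fixed = TRUE))
  co <- as.data.frame(stats::coef(summary(fit)))
  fixed <- tibble::tibble(
    term = rownames(co), estimate = co[["Estimate"]],
    se = co[["Std. Error"]], df = co[["df"]],
    statistic = co[["t value"]], p = co[["Pr(>|t|)"]]
  )
  vc <- lme4::VarCorr(fit)[[subject]]
  ranef_cov <- matrix(as.numeric(vc), nrow = nrow(vc),
                      dimnames = dimnames(vc))
  structure(list(fixed = fixed, ranef_cov = ranef_cov, converged = converged,
                 reduced_random = reduced, fit = fit, formula = fml),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>", deparse(x$formula), "\n")
  if (!x$converged) cat("  ** did not converge cleanly **\n")
  if (x$reduced_random) cat("  (random structure reduced to intercept-only)\n")
  print(x$fixed)
  invisible(x)
}

#' Covariate-adjusted partial correlation
#'
#' Residualises `x` and `y` on an intercept plus the covariate by least
#' squares (ranks are taken first for the Spearman variant) and correlates
#' the residuals; the p-value uses the t transform on n - 3 degrees of
#' freedom (one df lost to the covariate).
#'
#' @param data Data frame.
#' @param x,y,covariate Column names.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble of class `partial_corr_result`: `method`,
#'   `estimate`, `statistic`, `df`, `p`, `n`, `covariate`.
#' @export
partial_corr <- function(data, x, y, covariate = "pds",
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), all(c(x, y, covariate) %in% names(data)))
  d <- data[stats::complete.cases(data[, c(x, y, covariate)]), c(x, y, covariate)]
  n <- nrow(d)
  if (n < 5L) stop("need at least 5 complete observations")
  xv <- d[[x]]; yv <- d[[y]]; zv <- d[[covariate]]
  if (method == "spearman") {
    xv <- rank(xv); yv <- rank(yv); zv <- rank(zv)
  }
  Z <- cbind(1, zv)
  rx <- stats::lm.fit(Z, xv)$residuals
  ry <- stats::lm.fit(Z, yv)$residuals
  tol_x <- 1e-10 * max(stats::sd(xv), 1)
  tol_y <- 1e-10 * max(stats::sd(yv), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y) {
    stop("constant input after residualisation")
  }
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tt <- r * sqrt(df / (1 - r^2))
  out <- tibble::tibble(method = method, estimate = r, statistic = tt,
                        df = df, p = 2 * stats::pt(-abs(tt), df),
                        n = n, covariate = covariate)
  class(out) <- c("partial_corr_result", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values. The
#' family is always an explicit input: callers pass exactly the set of tests
#' run together.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}
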