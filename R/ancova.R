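#' Two-group ANCOVA with a continuous covariate
#'
#' Fits `value ~ covariate + group` by least squares and reports the F test
#' of the group factor adjusted for the covariate, with eta-squared
#' (SS_group / SS_total, group SS adjusted for the covariate) and partial
#' eta-squared. With two groups the group term has 1 numerator df and
#' n - 3 denominator df.
#'
#' @param data A data frame.
#' @param value,group,covariate Column names (character).
#' @return A one-row tibble of class `ancova_result`: `term`, `F`, `df1`,
#'   `df2`, `p`, `eta_sq`, `eta_sq_partial`.
#' @export
ancova_group <- function(data, value, group = "group", covariate = "pds") {
  stopifnot(is.data.frame(data), all(c(value, group, covariate) %in% names(data)))
  y <- data[[value]]; g <- factor(data[[group]]); z <- data[[covariate]]
  stopifnot(all(is.finite(y)), all(is.finite(z)))
  if (nlevels(g) < 2L) stop("group factor needs at least 2 levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 subjects")
  X <- stats::model.matrix(~ z + g)
  if (qr(X)$rank < ncol(X)) {
    stop("covariate collinear with the group indicator; ANCOVA not identifiable")
  }
  fit <- stats::lm(y ~ z + g)
  an <- stats::anova(fit)  # sequential: covariate first, so group is adjusted
  ss <- an[["Sum Sq"]]
  ss_group <- ss[2]; ss_res <- ss[3]; ss_total <- sum(ss)
  Fv <- an[["F value"]][2]
  out <- tibble::tibble(
    term = group,
    F = Fv,
    df1 = an[["Df"]][2],
    df2 = an[["Df"]][3],
    p = an[["Pr(>F)"]][2],
    eta_sq = ss_group / ss_total,
    eta_sq_partial = ss_group / (ss_group + ss_res)
  )
  class(out) <- c("ancova_result", class(out))
  out
}

#' Leave-one-ROI-out MANOVA sensitivity analysis
#'
#' For each region in `roi_cols`, omits that region and fits a multivariate
#' linear model of the remaining RS columns on the covariate and group,
#' summarising the group effect (adjusted for the covariate) with Wilks'
#' lambda computed from explicit error / hypothesis SSCP matrices. For a
#' one-df group contrast the F transformation of Wilks' lambda is exact:
#' with p retained regions and error df `n - 3`,
#' `F = ((1 - lambda) / lambda) * (df_e - p + 1) / p` on `(p, df_e - p + 1)`
#' df. With a single retained region the result reduces exactly to the
#' univariate ANCOVA.
#'
#' @param data Data frame with one row per subject.
#' @param roi_cols Character vector (>= 2) of per-ROI RS column names.
#' @param group,covariate Column names.
#' @return Tibble with one row per omitted ROI: `omitted`, `wilks`, `F`,
#'   `df1`, `df2`, `p`.
#' @export
leave_one_roi_out_manova <- function(data, roi_cols, group = "group",
                                     covariate = "pds") {
  stopifnot(is.data.frame(data), length(roi_cols) >= 2L,
            all(c(roi_cols, group, covariate) %in% names(data)))
  n <- nrow(data)
  if (n <= length(roi_cols) + 3L) {
    stop("too few subjects for the number of ROI columns")
  }
  purrr::map_dfr(roi_cols, function(omit) {
    keep <- setdiff(roi_cols, omit)
    res <- wilks_group_test(data, keep, group, covariate)
    tibble::tibble(omitted = omit, wilks = res$lambda, F = res$F,
                   df1 = res$df1, df2 = res$df2, p = res$p)
  })
}

# Wilks' lambda for the group term adjusted for the covariate, from SSCP
# matrices of the full vs covariate-only model fits.
wilks_group_test <- function(data, cols, group, covariate) {
  Y <- as.matrix(data[, cols, drop = FALSE])
  g <- factor(data[[group]]); z <- data[[covariate]]
  if (nlevels(g) != 2L) stop("expected a two-level group factor")
  X_full <- stats::model.matrix(~ z + g)
  X_red <- stats::model.matrix(~ z)
  E <- crossprod(stats::lm.fit(X_full, Y)$residuals)
  E_red <- crossprod(stats::lm.fit(X_red, Y)$residuals)
  Hm <- E_red - E
  p <- length(cols)
  df_e <- nrow(Y) - ncol(X_full)
  det_e <- det(E)
  if (!is.finite(det_e) || det_e <= 0) {
    stop(sprintf("singular within-group covariance for ROI set {%s}",
                 paste(cols, collapse = ", ")))
  }
  lambda <- det_e / det(E + Hm)
  df2 <- df_e - p + 1
  if (df2 <= 0) stop("not enough error df for the retained ROI set")
  Fv <- ((1 - lambda) / lambda) * df2 / p
  list(lambda = lambda, F = Fv, df1 = p, df2 = df2,
       p = stats::pf(Fv, p, df2, lower.tail = FALSE))
}
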