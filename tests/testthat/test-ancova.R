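toy8 <- tibble::tibble(
  y = c(1.2, 0.8, 1.5, 1.1, 2.3, 1.9, 2.6, 2.0),
  group = rep(c("AN", "CON"), each = 4),
  pds = c(8, 12, 15, 10, 9, 13, 14, 11))

test_that("identical group distributions give F near zero", {
  d <- tibble::tibble(y = rep(c(1, 2, 4, 3), 2),
                      group = rep(c("AN", "CON"), each = 4),
                      pds = rep(c(6, 9, 12, 15), 2))
  res <- ancova_group(d, "y")
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("ANCOVA matches an explicit normal-equations oracle", {
  res <- ancova_group(toy8, "y")
  # oracle: full vs reduced model by direct matrix algebra
  X_full <- cbind(1, toy8$pds, as.numeric(toy8$group == "CON"))
  X_red <- cbind(1, toy8$pds)
  rss <- function(X, y) {
    b <- solve(t(X) %*% X) %*% t(X) %*% y
    sum((y - X %*% b)^2)
  }
  rss_f <- rss(X_full, toy8$y); rss_r <- rss(X_red, toy8$y)
  F_oracle <- (rss_r - rss_f) / (rss_f / (8 - 3))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$df1, 1L)
  expect_equal(res$df2, 5L)
  expect_equal(res$p, pf(F_oracle, 1, 5, lower.tail = FALSE), tolerance = 1e-10)
  # eta^2 = adjusted group SS over total SS
  ss_tot <- sum((toy8$y - mean(toy8$y))^2)
  expect_equal(res$eta_sq, (rss_r - rss_f) / ss_tot, tolerance = 1e-10)
})

test_that("the group F equals the squared t of the group coefficient", {
  res <- ancova_group(toy8, "y")
  fit <- lm(y ~ pds + group, data = toy8)
  expect_equal(res$F, summary(fit)$coefficients["groupCON", "t value"]^2,
               tolerance = 1e-10)
})

test_that("ANCOVA F is invariant to affine rescaling of the covariate", {
  r1 <- ancova_group(toy8, "y")
  d2 <- dplyr::mutate(toy8, pds = 3.7 * pds - 12)
  r2 <- ancova_group(d2, "y")
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  expect_equal(r1$eta_sq, r2$eta_sq, tolerance = 1e-10)
})

test_that("a covariate collinear with group is rejected", {
  d <- dplyr::mutate(toy8, pds = as.numeric(group == "CON"))
  expect_error(ancova_group(d, "y"), "collinear")
})

test_that("MANOVA gives Wilks near 1 when groups are interchangeable", {
  d <- tibble::tibble(
    r1 = rep(c(1, 2, 5, 4, 3), 2), r2 = rep(c(2, 1, 4, 3, 6), 2),
    r3 = rep(c(0, 1, 0, 1, 2), 2),
    group = rep(c("AN", "CON"), each = 5),
    pds = rep(c(6, 8, 10, 12, 14), 2))
  res <- leave_one_roi_out_manova(d, c("r1", "r2", "r3"))
  expect_equal(nrow(res), 3L)
  expect_equal(res$wilks, rep(1, 3), tolerance = 1e-12)
  expect_equal(res$F, rep(0, 3), tolerance = 1e-10)
})

test_that("Wilks matches the determinant-ratio oracle and anova.mlm", {
  withr::with_seed(70, {
    d <- tibble::tibble(
      r1 = rnorm(16), r2 = rnorm(16), r3 = rnorm(16),
      group = rep(c("AN", "CON"), each = 8), pds = runif(16, 5, 20))
  })
  res <- leave_one_roi_out_manova(d, c("r1", "r2", "r3"))
  for (omit in c("r1", "r2", "r3")) {
    keep <- setdiff(c("r1", "r2", "r3"), omit)
    # determinant-ratio oracle from explicit SSCP matrices
    Y <- as.matrix(d[, keep])
    Xf <- cbind(1, d$pds, as.numeric(d$group == "CON"))
    Xr <- Xf[, 1:2]
    Ef <- crossprod(Y - Xf %*% solve(crossprod(Xf), crossprod(Xf, Y)))
    Er <- crossprod(Y - Xr %*% solve(crossprod(Xr), crossprod(Xr, Y)))
    lam <- det(Ef) / det(Er)
    expect_equal(res$wilks[res$omitted == omit], lam, tolerance = 1e-10)
    # independent route: stats::anova.mlm sequential Wilks
    fit <- stats::lm(Y ~ pds + group, data = d)
    tab <- stats::anova(fit, test = "Wilks")
    expect_equal(res$wilks[res$omitted == omit], tab["group", "Wilks"],
                 tolerance = 1e-8)
    expect_equal(res$p[res$omitted == omit],
                 tab["group", "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("MANOVA with one retained ROI reduces to the univariate ANCOVA", {
  withr::with_seed(71, {
    d <- tibble::tibble(
      r1 = rnorm(14), r2 = rnorm(14) + rep(c(0, 1), each = 7),
      group = rep(c("AN", "CON"), each = 7), pds = runif(14, 5, 20))
  })
  res <- leave_one_roi_out_manova(d, c("r1", "r2"))
  a2 <- ancova_group(d, "r2")
  expect_equal(res$F[res$omitted == "r1"], a2$F, tolerance = 1e-10)
  expect_equal(res$p[res$omitted == "r1"], a2$p, tolerance = 1e-10)
})

test_that("a singular within-group covariance errors with the ROI set named", {
  d <- tibble::tibble(
    r1 = rnorm(12), group = rep(c("AN", "CON"), each = 6),
    pds = runif(12, 5, 20))
  d$r2 <- d$r1          # exact collinearity -> singular E
  d$r3 <- rnorm(12)
  expect_error(leave_one_roi_out_manova(d, c("r1", "r2", "r3")), "singular")
})
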