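make_long <- function(n_subj = 15, months = 0:6, fun, seed = 1) {
  withr::with_seed(seed, {
    rs <- runif(n_subj, 0, 0.6)
    pds <- runif(n_subj, 5, 20)
    tidyr::expand_grid(i = seq_len(n_subj), time = months) |>
      dplyr::mutate(subject_id = sprintf("s%02d", i),
                    rs_cross = rs[i], rs_neutral = rs[i], pds = pds[i],
                    value = fun(time, rs[i], pds[i])) |>
      dplyr::select(-"i")
  })
}

test_that("a deterministic linear trend is recovered with a null interaction", {
  d <- make_long(12, 0:6, function(t, rs, pds) 2 + 0.5 * t)
  d$adjusted_bmi <- d$value
  # the exactly deterministic outcome makes the variance components
  # degenerate; the optimizer complaints are expected and harmless here
  fit <- suppressWarnings(fit_lmm(d, preset = "adjusted_bmi"))
  fx <- fit$fixed
  expect_equal(fx$estimate[fx$term == "(Intercept)"], 2, tolerance = 1e-6)
  expect_equal(fx$estimate[fx$term == "time"], 0.5, tolerance = 1e-6)
  expect_equal(fx$estimate[fx$term == "time:rs_cross"], 0, tolerance = 1e-6)
  # with a little residual noise the fit is well conditioned and converges
  d2 <- d
  withr::with_seed(99, d2$adjusted_bmi <- d2$value + rnorm(nrow(d2), 0, 0.1))
  fit2 <- fit_lmm(d2, preset = "adjusted_bmi")
  expect_true(fit2$converged)
  expect_equal(fit2$fixed$estimate[fit2$fixed$term == "time"], 0.5,
               tolerance = 0.05)
})

test_that("two-timepoint presets reduce the random structure and say so", {
  d <- make_long(12, c(0, 6), function(t, rs, pds) 3 + 0.1 * t + rnorm(1, 0, 0.2))
  d$ede <- d$value
  expect_message(fit <- fit_lmm(d, preset = "ede"), "intercept-only")
  expect_true(fit$reduced_random)
  expect_equal(dim(fit$ranef_cov), c(1L, 1L))
})

test_that("the BAS preset has no interaction term", {
  d <- make_long(12, c(0, 6), function(t, rs, pds) 30 + t + rnorm(1))
  d$bas <- d$value
  fit <- suppressWarnings(suppressMessages(fit_lmm(d, preset = "bas")))
  expect_false(any(grepl(":", fit$fixed$term)))
  expect_true("rs_neutral" %in% fit$fixed$term)
})

test_that("the random-effects covariance is symmetric PSD", {
  d <- make_long(20, 0:6, function(t, rs, pds) 2 + 0.5 * t + rnorm(1, 0, 0.5))
  d$adjusted_bmi <- d$value + rnorm(nrow(d), 0, 0.3)
  fit <- fit_lmm(d, preset = "adjusted_bmi")
  expect_equal(fit$ranef_cov, t(fit$ranef_cov))
  expect_true(all(eigen(fit$ranef_cov, symmetric = TRUE)$values > -1e-8))
})

test_that("a constant covariate reduces partial to plain correlation", {
  withr::with_seed(100, d <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = 1))
  pc <- partial_corr(d, "a", "b", "c")
  expect_equal(pc$estimate, cor(d$a, d$b), tolerance = 1e-10)
})

test_that("partial correlation matches the residualise-then-correlate oracle", {
  d <- tibble::tibble(
    x = c(1.0, 2.2, 3.1, 4.5, 5.2, 6.8),
    y = c(2.1, 1.9, 3.8, 3.2, 5.5, 5.1),
    z = c(0.5, 1.0, 1.2, 2.0, 2.4, 3.0))
  pc <- partial_corr(d, "x", "y", "z")
  Z <- cbind(1, d$z)
  H <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  rx <- d$x - H %*% d$x; ry <- d$y - H %*% d$y
  r_oracle <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  expect_equal(pc$estimate, r_oracle, tolerance = 1e-10)
  t_oracle <- r_oracle * sqrt(3 / (1 - r_oracle^2))
  expect_equal(pc$p, 2 * pt(-abs(t_oracle), 3), tolerance = 1e-10)
})

test_that("partial correlation is symmetric and Spearman is rank-invariant", {
  withr::with_seed(101, d <- tibble::tibble(x = rnorm(25), y = rnorm(25),
                                            z = runif(25)))
  expect_equal(partial_corr(d, "x", "y", "z")$estimate,
               partial_corr(d, "y", "x", "z")$estimate, tolerance = 1e-12)
  d2 <- dplyr::mutate(d, x = exp(x), y = y^3)
  expect_equal(partial_corr(d, "x", "y", "z", method = "spearman")$estimate,
               partial_corr(d2, "x", "y", "z", method = "spearman")$estimate,
               tolerance = 1e-12)
})

test_that("degenerate partial-correlation inputs error", {
  d <- tibble::tibble(x = rep(1, 10), y = rnorm(10), z = rnorm(10))
  expect_error(partial_corr(d, "x", "y", "z"), "constant")
  expect_error(partial_corr(d[1:4, ], "y", "z", "x"), "at least 5")
})

test_that("partial-correlation p-values are uniform under the null", {
  withr::with_seed(102, {
    ps <- vapply(1:200, function(i) {
      d <- tibble::tibble(z = rnorm(30), x = 0.5 * z + rnorm(30),
                          y = -0.5 * z + rnorm(30))
      partial_corr(d, "x", "y", "z")$p
    }, numeric(1))
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.028, 0.098, 0.345)), c(0.084, 0.147, 0.345),
               tolerance = 1e-12)
  expect_equal(bh_fdr(0.031), 0.031)
  p <- c(0.01, 0.04, 0.03, 0.02)
  # oracle: adjusted_i = min over j >= rank(i) of m p_(j) / j, capped at 1
  m <- length(p)
  ord <- order(p)
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p[ord][i:m] / (i:m)))
  }, numeric(1))
  oracle <- numeric(m); oracle[ord] <- adj_sorted
  expect_equal(bh_fdr(p), oracle, tolerance = 1e-12)
})

test_that("BH is monotone, order-preserving and never below the raw p", {
  withr::with_seed(103, p <- sort(runif(12)))
  a <- bh_fdr(p)
  expect_true(all(diff(a) >= -1e-12))   # sorted in, sorted out
  expect_true(all(a >= p))
  expect_true(all(a <= 1))
  # order preservation on unsorted input (ties in the adjusted values allowed)
  withr::with_seed(104, p2 <- runif(9))
  expect_true(all(diff(bh_fdr(p2)[order(p2)]) >= -1e-12))
})
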