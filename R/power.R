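#' Fixed-effects F-test power query
#'
#' Describes the design of a between-group F test with covariates: the
#' group term has `n_groups - 1` numerator df and
#' `n_total - n_groups - n_covariates` denominator df, and the
#' noncentrality parameter is `lambda = f^2 * n_total` for Cohen's effect
#' size f.
#'
#' @param alpha Type-I error rate.
#' @param power Target power (1 - beta).
#' @param n_total Total sample size.
#' @param n_groups Number of groups.
#' @param n_covariates Number of continuous covariates.
#' @return A list of class `power_query`.
#' @export
power_query <- function(alpha = 0.05, power = 0.80, n_total = 47L,
                        n_groups = 2L, n_covariates = 1L) {
  df2 <- n_total - n_groups - n_covariates
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, df2 > 0, n_groups >= 2)
  structure(list(alpha = alpha, power = power, n_total = as.integer(n_total),
                 n_groups = as.integer(n_groups),
                 n_covariates = as.integer(n_covariates),
                 df1 = as.integer(n_groups - 1L), df2 = as.integer(df2)),
            class = "power_query")
}

#' Achieved power of the group F test at effect size f
#'
#' Survival probability of the noncentral F distribution (noncentrality
#' `f^2 * n_total`) at the central critical value `qf(1 - alpha, df1, df2)`.
#'
#' @param f Cohen's f (>= 0).
#' @param query A [power_query()].
#' @return Achieved power in \[alpha, 1\].
#' @export
f_test_power <- function(f, query = power_query()) {
  stopifnot(inherits(query, "power_query"), all(f >= 0))
  crit <- stats::qf(1 - query$alpha, query$df1, query$df2)
  stats::pf(crit, query$df1, query$df2, ncp = f^2 * query$n_total,
            lower.tail = FALSE)
}

#' Minimum detectable effect size f
#'
#' Smallest Cohen's f whose achieved power reaches the query's target,
#' solved by bisection on the noncentral-F survival function (power is
#' strictly increasing in f).
#'
#' @param query A [power_query()].
#' @param tol Bisection tolerance on f.
#' @return Cohen's f.
#' @export
solve_detectable_f <- function(query = power_query(), tol = 1e-6) {
  stopifnot(inherits(query, "power_query"))
  lo <- 0; hi <- 1
  while (f_test_power(hi, query) < query$power) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f_test_power(mid, query) >= query$power) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
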