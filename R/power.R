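#' Achieved power of a one-sample or paired t-test
#'
#' Power is computed from the noncentral t distribution with
#' noncentrality `ncp = d * sqrt(n)` and `n - 1` degrees of freedom. For
#' two-tailed tests both rejection regions are counted (the far-tail term
#' matters at large effect sizes).
#'
#' @param n Sample size: number of stances (one-sample) or of pairs
#'   (paired differences); the two families share this power function.
#' @param d Cohen's d effect size (> 0).
#' @param alpha Type-I level; default 0.05.
#' @param tails 1 or 2.
#' @return Achieved power in (0, 1).
#' @export
t_test_power <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  ncp <- d * sqrt(n)
  df <- n - 1
  if (tails == 1) {
    1 - pt(qt(1 - alpha, df), df, ncp = ncp)
  } else {
    tc <- qt(1 - alpha / 2, df)
    (1 - pt(tc, df, ncp = ncp)) + pt(-tc, df, ncp = ncp)
  }
}

#' Required number of steps (stances) for a t-test
#'
#' Smallest n whose achieved noncentral-t power reaches the target. With
#' the defaults of the in-shoe protocol this reproduces the familiar
#' requirements: 19 stances for the per-cell one-sample test against the
#' 200 kPa threshold (one tail, d = 0.6) and 24 stances for the paired
#' per-cell comparison between insoles (two tails, d = 0.6).
#'
#' @param d Cohen's d effect size.
#' @param alpha Type-I level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @param family `"one_sample_t"` or `"paired_t"` (label only: n counts
#'   stances in the first case and stance pairs in the second; the power
#'   function is the same noncentral-t form).
#' @param n_max Search cap.
#' @return Tibble with `family`, `tails`, `d`, `alpha`, `target_power`,
#'   `n`, `achieved_power`.
#' @export
required_n_t <- function(d, alpha = 0.05, power = 0.8, tails = 2,
                         family = c("paired_t", "one_sample_t"),
                         n_max = 1e6) {
  family <- match.arg(family)
  if (d <= 0) abort("effect size d must be > 0", class = "qsf_power_error")
  stopifnot(power > 0, power < 1)
  n <- 2L
  while (t_test_power(n, d, alpha, tails) < power) {
    n <- n + 1L
    if (n > n_max) abort("no n below n_max reaches the target power",
                         class = "qsf_power_error")
  }
  tibble::tibble(family = family, tails = tails, d = d, alpha = alpha,
                 target_power = power, n = n,
                 achieved_power = t_test_power(n, d, alpha, tails))
}

#' Smallest detectable effect size at a given number of steps
#'
#' Sensitivity analysis: the d at which the achieved power equals the
#' target, solved by monotone bisection on the noncentral-t power
#' function. Recording 24 stances instead of the one-sample minimum of 19
#' lowers the detectable one-tailed effect from d = 0.6 to d = 0.52.
#'
#' @param n Number of stances (>= 2).
#' @inheritParams required_n_t
#' @param tol Bisection tolerance on power; default 1e-6.
#' @return Tibble with `n`, `tails`, `alpha`, `target_power`, `d`,
#'   `achieved_power`.
#' @export
detectable_d <- function(n, alpha = 0.05, power = 0.8, tails = 1,
                         family = c("one_sample_t", "paired_t"), tol = 1e-6) {
  family <- match.arg(family)
  stopifnot(n >= 2)
  lo <- 1e-6; hi <- 1
  while (t_test_power(n, hi, alpha, tails) < power) hi <- hi * 2
  while (TRUE) {
    mid <- (lo + hi) / 2
    pw <- t_test_power(n, mid, alpha, tails)
    if (abs(pw - power) <= tol || (hi - lo) < 1e-12) break
    if (pw < power) lo <- mid else hi <- mid
  }
  tibble::tibble(family = family, n = n, tails = tails, alpha = alpha,
                 target_power = power, d = mid,
                 achieved_power = t_test_power(n, mid, alpha, tails))
}

#' Nonparametric sample-size inflation (+15\% rule)
#'
#' Rule of thumb for sizing a nonparametric repeated-measures analysis
#' (e.g. the Friedman test) from the corresponding parametric requirement:
#' add 15\%. For the cohort design, 41 feet inflate to 47.15.
#'
#' @param n_parametric Parametric sample size (> 0).
#' @return Tibble with `n_parametric`, `n_raw` (x 1.15), `n_ceiling`.
#' @export
nonparametric_inflate <- function(n_parametric) {
  if (!is.numeric(n_parametric) || n_parametric <= 0) {
    abort("n_parametric must be > 0", class = "qsf_power_error")
  }
  raw <- n_parametric * 1.15
  tibble::tibble(n_parametric = n_parametric, n_raw = raw,
                 n_ceiling = ceiling(raw))
}

#' Required sample size for a within-subject repeated-measures ANOVA
#'
#' Noncentral-F power with the conventional within-factor
#' parameterisation: numerator df `(k - 1) * epsilon`, denominator df
#' `(n - 1) * (k - 1) * epsilon`, noncentrality
#' `lambda = n * k * f^2 * epsilon / (1 - rho)`, where `rho` is the mean
#' correlation among repeated measures and `epsilon` the nonsphericity
#' correction. Conventions for this design vary across calculators, so
#' `rho` and `epsilon` must be given explicitly.
#'
#' @param f Cohen's f effect size (> 0). `f = d / 2` for a two-level
#'   contrast.
#' @param k Number of repeated measurements (>= 2).
#' @param alpha Type-I level.
#' @param power Target power.
#' @param rho Correlation among repeated measures, in (0, 1).
#' @param epsilon Nonsphericity correction, in (0, 1].
#' @param n_max Search cap.
#' @return Tibble with the spec and `n`, `achieved_power`.
#' @export
required_n_rm_anova <- function(f, k, alpha = 0.05, power = 0.8,
                                rho = 0.5, epsilon = 1, n_max = 1e6) {
  if (f <= 0) abort("effect size f must be > 0", class = "qsf_power_error")
  if (k < 2) abort("k must be >= 2", class = "qsf_power_error")
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)", class = "qsf_power_error")
  if (epsilon <= 0 || epsilon > 1) {
    abort("epsilon must be in (0, 1]", class = "qsf_power_error")
  }
  pow <- function(n) {
    df1 <- (k - 1) * epsilon
    df2 <- (n - 1) * (k - 1) * epsilon
    lambda <- n * k * f^2 * epsilon / (1 - rho)
    1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lambda)
  }
  n <- 2L
  while (pow(n) < power) {
    n <- n + 1L
    if (n > n_max) abort("no n below n_max reaches the target power",
                         class = "qsf_power_error")
  }
  tibble::tibble(f = f, k = k, alpha = alpha, target_power = power,
                 rho = rho, epsilon = epsilon, n = n, achieved_power = pow(n))
}
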