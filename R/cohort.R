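#' Friedman test on a per-foot area table
#'
#' Nonparametric repeated-measures comparison of total R-ROI areas across
#' walking conditions (each foot is its own block). Within-row ties get
#' midranks and the chi-square statistic carries the tie correction --
#' important here because feet with complete offloading contribute many
#' zero areas.
#'
#' The chi-square approximation is coarse for a handful of feet, so by
#' default (`mode = "auto"`) the exact permutation p-value is computed for
#' up to three conditions: the statistic depends on the rank column sums
#' only, whose exact null distribution follows by convolving the per-foot
#' rank arrangements (uniform over the within-row permutations).
#'
#' @param table A `qsf_area_table` (see [as_area_table()]).
#' @param conditions Character vector of condition columns (k >= 2).
#' @param mode `"auto"` (exact for k <= 3, else approximation), `"exact"`,
#'   or `"approx"` (tie-corrected chi-square).
#' @return Tibble with `statistic` (tie-corrected chi-square), `df`, `p.value`,
#'   `n` (feet), `k` (conditions), `method`.
#' @export
friedman_area_test <- function(table, conditions,
                               mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  X <- area_matrix(table, conditions)
  n <- nrow(X); k <- ncol(X)
  if (n < 2L) abort("need at least 2 complete feet", class = "qsf_stats_error")
  R <- t(apply(X, 1L, rank))  # midranks within each foot
  Rj <- colSums(R)
  stat <- 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1)) over tie groups per row
  tie_sum <- sum(apply(X, 1L, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  stat_c <- if (C <= 0) 0 else stat / C  # fully tied rows carry no evidence
  if (mode == "auto") mode <- if (k <= 3L) "exact" else "approx"
  if (mode == "exact") {
    if (k > 3L) {
      abort("exact Friedman p is implemented for k <= 3 conditions",
            class = "qsf_stats_error")
    }
    p <- friedman_exact_p(R, stat)
    method <- "Friedman rank sum test (exact permutation)"
  } else {
    p <- if (C <= 0) 1 else pchisq_upper(stat_c, df = k - 1)
    method <- "Friedman rank sum test (tie-corrected chi-square)"
  }
  tibble::tibble(statistic = stat_c, df = k - 1, p.value = p, n = n, k = k,
                 method = method)
}

# Exact permutation p for the Friedman statistic, k <= 3. The statistic is
# a function of the rank column sums alone, so the null distribution is the
# convolution over rows of the (<= k!) equally likely rank arrangements.
# Doubled ranks keep midranks on an integer grid.
friedman_exact_p <- function(R, stat_obs) {
  n <- nrow(R); k <- ncol(R)
  perms3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  max1 <- 2L * k * n
  # dp over (2*S1 [, 2*S2]) as dense probability arrays
  if (k == 2L) {
    dp <- numeric(max1 + 1L)
    dp[1L] <- 1
    for (i in seq_len(n)) {
      r2 <- as.integer(round(2 * R[i, ]))
      opts <- unique(c(r2[1L], r2[2L]))
      w <- vapply(opts, function(o) mean(c(r2[1L], r2[2L]) == o), 0)
      new <- numeric(max1 + 1L)
      for (j in seq_along(opts)) {
        sh <- opts[j]
        new[(sh + 1L):(max1 + 1L)] <- new[(sh + 1L):(max1 + 1L)] +
          w[j] * dp[1L:(max1 + 1L - sh)]
      }
      dp <- new
    }
    s1 <- (0:max1) / 2
    s2 <- n * (k + 1) / 2 * 2 - s1  # total rank sum fixed at n*(k+1)/2 per col pair
    stats <- 12 / (n * k * (k + 1)) *
      ((s1 - n * (k + 1) / 2)^2 + (s2 - n * (k + 1) / 2)^2)
    return(sum(dp[stats >= stat_obs - 1e-9]))
  }
  dp <- matrix(0, max1 + 1L, max1 + 1L)
  dp[1L, 1L] <- 1
  for (i in seq_len(n)) {
    r2 <- as.integer(round(2 * R[i, ]))
    pairs <- cbind(r2[perms3[, 1L]], r2[perms3[, 2L]])
    key <- paste(pairs[, 1L], pairs[, 2L])
    w <- table(key) / 6
    uniq <- do.call(rbind, strsplit(names(w), " "))
    new <- matrix(0, max1 + 1L, max1 + 1L)
    for (j in seq_len(nrow(uniq))) {
      a <- as.integer(uniq[j, 1L]); b <- as.integer(uniq[j, 2L])
      new[(a + 1L):(max1 + 1L), (b + 1L):(max1 + 1L)] <-
        new[(a + 1L):(max1 + 1L), (b + 1L):(max1 + 1L)] +
        as.numeric(w[j]) * dp[1L:(max1 + 1L - a), 1L:(max1 + 1L - b)]
    }
    dp <- new
  }
  nz <- which(dp > 0, arr.ind = TRUE)
  s1 <- (nz[, 1L] - 1L) / 2
  s2 <- (nz[, 2L] - 1L) / 2
  s3 <- n * k * (k + 1) / 2 - s1 - s2
  stats <- 12 / (n * k * (k + 1)) *
    ((s1 - n * (k + 1) / 2)^2 + (s2 - n * (k + 1) / 2)^2 +
       (s3 - n * (k + 1) / 2)^2)
  sum(dp[nz][stats >= stat_obs - 1e-9])
}

pchisq_upper <- function(q, df) stats::pchisq(q, df = df, lower.tail = FALSE)

area_matrix <- function(table, conditions) {
  if (length(conditions) < 2L) {
    abort("need at least 2 conditions", class = "qsf_stats_error")
  }
  missing_cols <- setdiff(conditions, names(table))
  if (length(missing_cols)) {
    abort(paste0("conditions not in table: ", paste(missing_cols, collapse = ", ")),
          class = "qsf_stats_error")
  }
  X <- as.matrix(as.data.frame(table)[conditions])
  if (anyNA(X)) abort("incomplete rows in area table", class = "qsf_stats_error")
  X
}

#' Paired Wilcoxon signed-rank test
#'
#' Classic signed-rank policy: zero differences are dropped, ties among
#' absolute differences get midranks. `mode = "auto"` uses exact
#' enumeration for n <= 25 without ties and the normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors (e.g. per-foot areas in two
#'   conditions).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return Tibble with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_effective` (pairs after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "qsf_stats_error")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warn("all paired differences are zero; p = 1")
    return(tibble::tibble(statistic = 0, p.value = 1, n_effective = 0L,
                          method = "Wilcoxon signed rank (degenerate)"))
  }
  if (n < 5L) {
    warn("fewer than 5 non-zero differences; signed-rank p is very coarse")
  }
  has_ties <- anyDuplicated(abs(d)) > 0L
  exact <- switch(mode, auto = n <= 25L && !has_ties, exact = TRUE, approx = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
                 n_effective = n,
                 method = if (exact) "Wilcoxon signed rank (exact)"
                          else "Wilcoxon signed rank (normal approx., cc)")
}

#' Full group-level comparison of R-ROI areas
#'
#' The omnibus Friedman test followed by all pairwise Wilcoxon signed-rank
#' tests with Bonferroni family-level control: each pairwise test is
#' evaluated at `alpha_family / n_pairs` (0.05 / 3 = 0.016667 for three
#' conditions). Mean per-pair differences of areas (condition1 -
#' condition2, cm^2) are reported alongside the rank-based p-values.
#'
#' @param table A `qsf_area_table`.
#' @param conditions Condition columns to compare (k >= 2).
#' @param alpha_family Family-wise type-I level; default 0.05.
#' @return An object of class `qsf_group_comparison`.
#' @export
compare_conditions <- function(table, conditions, alpha_family = 0.05) {
  X <- area_matrix(table, conditions)
  k <- length(conditions)
  fr <- friedman_area_test(table, conditions)
  pairs <- utils::combn(conditions, 2L, simplify = FALSE)
  alpha_pairwise <- alpha_family / length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    w <- suppressWarnings(wilcoxon_signed_rank(X[, pr[1L]], X[, pr[2L]]))
    tibble::tibble(condition1 = pr[1L], condition2 = pr[2L],
                   statistic = w$statistic, p.value = w$p.value,
                   mean_difference_cm2 = mean(X[, pr[1L]]) - mean(X[, pr[2L]]),
                   significant = w$p.value < alpha_pairwise)
  })
  structure(list(k = k, n = nrow(X), conditions = conditions,
                 friedman = fr, pairwise = pw,
                 alpha_family = alpha_family, alpha_pairwise = alpha_pairwise),
            class = "qsf_group_comparison")
}

#' @export
print.qsf_group_comparison <- function(x, ...) {
  cat(sprintf("<qsf_group_comparison> %d feet x %d conditions (%s)\n",
              x$n, x$k, paste(x$conditions, collapse = ", ")))
  cat(sprintf("  Friedman chi^2(%d) = %.3f, p = %.3g\n",
              x$friedman$df, x$friedman$statistic, x$friedman$p.value))
  cat(sprintf("  pairwise signed-rank at alpha = %.6f (Bonferroni)\n",
              x$alpha_pairwise))
  print(as.data.frame(x$pairwise), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy the pairwise table of a group comparison
#' @param x A `qsf_group_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise signed-rank results.
#' @export
tidy.qsf_group_comparison <- function(x, ...) x$pairwise

#' One-row summary of a group comparison
#' @param x A `qsf_group_comparison`.
#' @param ... Unused.
#' @return Tibble with the Friedman result and family alphas.
#' @export
glance.qsf_group_comparison <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k,
                 friedman_chi2 = x$friedman$statistic,
                 friedman_df = x$friedman$df,
                 friedman_p = x$friedman$p.value,
                 alpha_family = x$alpha_family,
                 alpha_pairwise = x$alpha_pairwise)
}

#' Count feet with complete R-ROI removal
#'
#' "Optimal" offloading performance means the condition leaves no residual
#' risk region, i.e. a total R-ROI area of exactly zero.
#'
#' @param table A `qsf_area_table`.
#' @param condition Condition column name.
#' @return Integer count of optimal feet.
#' @export
count_optimal <- function(table, condition) {
  if (!condition %in% names(table)) {
    abort(sprintf("condition '%s' not in table", condition),
          class = "qsf_stats_error")
  }
  sum(table[[condition]] == 0)
}

#' Per-condition descriptive statistics of R-ROI areas
#'
#' @param table A `qsf_area_table`.
#' @param conditions Condition columns; default all non-key columns.
#' @return Tibble with `condition`, `n`, `mean`, `sd`, `median`, `max`
#'   (cm^2). `sd` is `NA` for a single foot.
#' @export
area_descriptives <- function(table, conditions = NULL) {
  conditions <- conditions %||% setdiff(names(table), c("subject", "side"))
  purrr::map_dfr(conditions, function(cc) {
    v <- table[[cc]]
    tibble::tibble(condition = cc, n = length(v), mean = mean(v),
                   sd = if (length(v) > 1L) sd(v) else NA_real_,
                   median = median(v), max = max(v))
  })
}
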