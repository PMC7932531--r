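#' R-ROI determination configuration
#'
#' Cells of the mean peak pressure map are tested against the 200 kPa
#' ulceration-risk threshold. Because the published record of this method
#' does not pin down the exact per-cell statistic, four rules are offered:
#' \describe{
#'   \item{`not_significantly_below`}{(default) keep a cell in the R-ROI
#'     unless a one-sample t-test shows its mean peak pressure to be
#'     significantly *below* the threshold. This is the conservative
#'     reading: near-threshold cells with high step-to-step variability are
#'     retained as at-risk.}
#'   \item{`significantly_above`}{keep only cells significantly above the
#'     threshold.}
#'   \item{`direct_threshold`}{plain `mean >= threshold` cut-off (the
#'     literature's naive rule the statistical rules improve on).}
#'   \item{`dispersion_band`}{keep cells with `mean >= threshold` or whose
#'     deficit is within `t_crit * SD` (SD, not SEM) of it.}
#' }
#' With any statistical rule, zero-variance cells are decided by direct
#' comparison of the mean to the threshold (the limit of the t-test).
#'
#' @param threshold_kpa Risk threshold; default 200 kPa.
#' @param alpha Type-I level of the per-cell test; default 0.05.
#' @param rule One of the four rules above.
#' @param connectivity 4 or 8 (default) neighbourhood for clustering.
#' @param p_adjust `"none"` (default; the per-cell tests are reported
#'   uncorrected) or any [stats::p.adjust()] method for sensitivity
#'   analysis across cells.
#' @return A list of class `qsf_rroi_config`.
#' @export
rroi_config <- function(threshold_kpa = 200, alpha = 0.05,
                        rule = c("not_significantly_below", "significantly_above",
                                 "direct_threshold", "dispersion_band"),
                        connectivity = 8, p_adjust = "none") {
  rule <- match.arg(rule)
  stopifnot(threshold_kpa > 0, alpha > 0, alpha < 1, connectivity %in% c(4, 8))
  structure(list(threshold_kpa = threshold_kpa, alpha = alpha, rule = rule,
                 connectivity = as.integer(connectivity), p_adjust = p_adjust),
            class = "qsf_rroi_config")
}

#' Classify cells as belonging to the risk region
#'
#' Vectorised over cells. For the statistical rules the statistic is
#' `t = (mean - threshold) / (sd / sqrt(n))` with `n - 1` degrees of
#' freedom and one-sided critical value `t_crit = qt(1 - alpha, n - 1)`.
#'
#' @param mean,sd Per-cell mean and sample SD of peak pressures (kPa).
#' @param n Number of stances behind the means.
#' @param cfg An [rroi_config()].
#' @return Logical vector/matrix, `TRUE` for R-ROI membership.
#' @export
classify_cells <- function(mean, sd, n, cfg = rroi_config()) {
  if (any(sd < 0)) abort("sd must be >= 0", class = "qsf_rroi_error")
  thr <- cfg$threshold_kpa
  if (cfg$rule == "direct_threshold") {
    if (n < 1) abort("n must be >= 1", class = "qsf_rroi_error")
    return(mean >= thr)
  }
  if (n < 2) {
    abort("statistical R-ROI rules need n >= 2 stances", class = "qsf_rroi_error")
  }
  t_crit <- qt(1 - cfg$alpha, df = n - 1)
  zero_var <- sd == 0
  tt <- (mean - thr) / (sd / sqrt(n))  # Inf/NaN on zero-variance, masked below
  res <- switch(cfg$rule,
    not_significantly_below = !(tt < -t_crit),
    significantly_above = tt > t_crit,
    dispersion_band = mean >= thr | (thr - mean) <= t_crit * sd)
  res[zero_var] <- mean[zero_var] >= thr
  res
}

# BFS connected-component labelling on a logical matrix, 4- or 8-connectivity
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  current <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      cell <- queue[1L]; queue <- queue[-1L]
      r <- ((cell - 1L) %% nr) + 1L
      cc <- ((cell - 1L) %/% nr) + 1L
      nb_r <- r + dr; nb_c <- cc + dc
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- current
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Build the R-ROI mask from a mean peak pressure map
#'
#' Applies [classify_cells()] to every cell of the MPPM (no anatomical
#' masking: the whole plantar surface is eligible), labels connected
#' clusters of risk cells, and computes the total risk area in cm^2.
#'
#' @param mppm A `qsf_mppm`.
#' @param cfg An [rroi_config()].
#' @return An object of class `qsf_rroi`: list with `grid`, `in_rroi`
#'   (logical matrix), `cluster_labels` (integer matrix, 0 = background),
#'   `n_clusters`, `total_area_cm2` and the `cfg` used.
#' @export
build_rroi <- function(mppm, cfg = rroi_config()) {
  stopifnot(inherits(mppm, "qsf_mppm"))
  mask <- classify_cells(mppm$mean, mppm$sd, mppm$n, cfg)
  if (cfg$p_adjust != "none" && cfg$rule %in%
        c("not_significantly_below", "significantly_above")) {
    tt <- (mppm$mean - cfg$threshold_kpa) / (mppm$sd / sqrt(mppm$n))
    p <- if (cfg$rule == "significantly_above") {
      1 - pt(tt, df = mppm$n - 1)
    } else {
      pt(tt, df = mppm$n - 1)  # evidence of being below threshold
    }
    p_adj <- matrix(stats::p.adjust(p, method = cfg$p_adjust), nrow(p), ncol(p))
    zero_var <- mppm$sd == 0
    mask <- if (cfg$rule == "significantly_above") p_adj < cfg$alpha
            else !(p_adj < cfg$alpha)
    mask[zero_var] <- mppm$mean[zero_var] >= cfg$threshold_kpa
  }
  labels <- label_components(mask, cfg$connectivity)
  structure(list(grid = mppm$grid, in_rroi = mask, cluster_labels = labels,
                 n_clusters = max(labels), cfg = cfg,
                 total_area_cm2 = sum(mask) * cell_area_cm2(mppm$grid)),
            class = "qsf_rroi")
}

#' @export
print.qsf_rroi <- function(x, ...) {
  cat(sprintf("<qsf_rroi> %d risk cells in %d cluster(s), total %.2f cm^2 (rule: %s)\n",
              sum(x$in_rroi), x$n_clusters, x$total_area_cm2, x$cfg$rule))
  invisible(x)
}

#' Tidy an R-ROI mask into a long tibble
#' @param x A `qsf_rroi`.
#' @param ... Unused.
#' @return One row per cell: coordinates, `in_rroi`, `cluster`.
#' @export
tidy.qsf_rroi <- function(x, ...) {
  dplyr::bind_cols(grid_cells(x$grid),
                   tibble::tibble(in_rroi = as.vector(t(x$in_rroi)),
                                  cluster = as.vector(t(x$cluster_labels))))
}

#' One-line summary of an R-ROI mask
#' @param x A `qsf_rroi`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `n_clusters`, `total_area_cm2`, `rule`,
#'   `threshold_kpa`, `alpha`.
#' @export
glance.qsf_rroi <- function(x, ...) {
  tibble::tibble(n_cells = sum(x$in_rroi), n_clusters = x$n_clusters,
                 total_area_cm2 = x$total_area_cm2, rule = x$cfg$rule,
                 threshold_kpa = x$cfg$threshold_kpa, alpha = x$cfg$alpha)
}

# vectorised per-cell paired / Welch t-tests on step-level peak values
cellwise_t <- function(X_ref, X_alt, paired = TRUE) {
  if (paired) {
    D <- X_alt - X_ref
    n <- ncol(D)
    m <- rowMeans(D)
    s <- apply(D, 1L, sd)
    tt <- m / (s / sqrt(n))
    df <- rep(n - 1, length(m))
  } else {
    n1 <- ncol(X_ref); n2 <- ncol(X_alt)
    m1 <- rowMeans(X_ref); m2 <- rowMeans(X_alt)
    v1 <- apply(X_ref, 1L, stats::var); v2 <- apply(X_alt, 1L, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    m <- m2 - m1
  }
  p <- 2 * pt(-abs(tt), df = df)
  # zero-variance cells: identical zero differences carry no evidence (p = 1);
  # an identical non-zero shift on every step is the t -> +/-Inf limit (p = 0)
  degen <- !is.finite(tt)
  p[degen] <- ifelse(m[degen] == 0, 1, 0)
  list(mean_diff = m, t = tt, p = p)
}

#' Pressure-redistribution map between two insole conditions
#'
#' Runs a two-sided paired t-test per grid cell on step-paired peak
#' pressures (step i under the reference insole vs step i under the
#' alternative). Cells are categorised as:
#' \describe{
#'   \item{`sig_decrease` / `sig_increase`}{significant change at `alpha`,
#'     by the sign of the mean (alt - ref) difference;}
#'   \item{`rroi_unchanged`}{reference R-ROI cells with no significant
#'     change (residual risk left untouched by the insole);}
#'   \item{`unchanged`}{everything else.}
#' }
#'
#' @param peaks_ref,peaks_alt Lists of `qsf_peak_map` for the two
#'   conditions, on a common grid.
#' @param rroi_ref `qsf_rroi` of the reference condition.
#' @param cfg An [rroi_config()] (only `alpha` is used).
#' @param paired Pair steps by order (default). `FALSE` uses a Welch
#'   two-sample test, for recordings whose step counts differ.
#' @return An object of class `qsf_redistribution`: list with `grid`,
#'   `category` (character matrix with values unchanged/sig_decrease/
#'   sig_increase/rroi_unchanged), `mean_diff`, `p` (matrices), `alpha`,
#'   `paired`.
#' @export
redistribution_map <- function(peaks_ref, peaks_alt, rroi_ref,
                               cfg = rroi_config(), paired = TRUE) {
  if (length(peaks_ref) < 2L || length(peaks_alt) < 2L) {
    abort("need at least 2 steps per condition", class = "qsf_redist_error")
  }
  g <- peaks_ref[[1L]]$grid
  for (m in c(peaks_ref, peaks_alt)) {
    if (!same_grid(m$grid, g)) {
      abort("peak maps are on different grids", class = "qsf_redist_error")
    }
  }
  if (paired && length(peaks_ref) != length(peaks_alt)) {
    abort(paste("paired redistribution requires equal step counts;",
                "set paired = FALSE for a Welch comparison"),
          class = "qsf_redist_error")
  }
  X_ref <- vapply(peaks_ref, function(m) as.vector(m$values),
                  numeric(g$n_rows * g$n_cols))
  X_alt <- vapply(peaks_alt, function(m) as.vector(m$values),
                  numeric(g$n_rows * g$n_cols))
  res <- cellwise_t(X_ref, X_alt, paired = paired)
  sig <- res$p < cfg$alpha
  cat <- ifelse(sig & res$mean_diff < 0, "sig_decrease",
                ifelse(sig & res$mean_diff > 0, "sig_increase",
                       ifelse(as.vector(rroi_ref$in_rroi), "rroi_unchanged",
                              "unchanged")))
  structure(list(
    grid = g,
    category = matrix(cat, g$n_rows, g$n_cols),
    mean_diff = matrix(res$mean_diff, g$n_rows, g$n_cols),
    p = matrix(res$p, g$n_rows, g$n_cols),
    alpha = cfg$alpha, paired = paired),
    class = "qsf_redistribution")
}

#' Tidy a redistribution map
#' @param x A `qsf_redistribution`.
#' @param ... Unused.
#' @return One row per cell: coordinates, `category`, `mean_diff_kpa`, `p`.
#' @export
tidy.qsf_redistribution <- function(x, ...) {
  dplyr::bind_cols(grid_cells(x$grid),
                   tibble::tibble(
                     category = factor(as.vector(t(x$category)),
                                       levels = c("unchanged", "sig_decrease",
                                                  "sig_increase",
                                                  "rroi_unchanged")),
                     mean_diff_kpa = as.vector(t(x$mean_diff)),
                     p = as.vector(t(x$p))))
}

#' Residual R-ROI pressure-reduction report
#'
#' Offloading is *optimal* for a foot when the alternative insole removes
#' the risk region entirely. For sub-optimal feet the mean peak pressure
#' over the residual R-ROI is compared with the mean over the reference
#' R-ROI. Since residual risk regions are determined where cells remain
#' at/above threshold, a lower bound on the achieved reduction is always
#' available as `mean(ref R-ROI) - threshold`.
#'
#' @param mppm_ref,mppm_alt `qsf_mppm` for the two conditions.
#' @param rroi_ref,rroi_alt Corresponding `qsf_rroi` masks on one grid.
#' @param cfg An [rroi_config()] (threshold used for the lower bound).
#' @return Tibble of class `qsf_reduction` with `optimal`,
#'   `mean_ref_kpa`, `mean_alt_kpa`, `mean_reduction_kpa`,
#'   `mean_reduction_pct`, `lower_bound_kpa`, `residual_area_cm2`.
#' @export
residual_reduction <- function(mppm_ref, rroi_ref, mppm_alt, rroi_alt,
                               cfg = rroi_config()) {
  if (!same_grid(rroi_ref$grid, rroi_alt$grid)) {
    abort("masks are on different grids", class = "qsf_reduction_error")
  }
  if (!any(rroi_ref$in_rroi)) {
    abort("no reference risk region", class = "qsf_reduction_error")
  }
  mean_ref <- mean(mppm_ref$mean[rroi_ref$in_rroi])
  optimal <- !any(rroi_alt$in_rroi)
  if (optimal) {
    mean_alt <- NA_real_; red <- NA_real_; pct <- NA_real_
  } else {
    mean_alt <- mean(mppm_alt$mean[rroi_alt$in_rroi])
    red <- mean_ref - mean_alt
    pct <- 100 * red / mean_ref
  }
  out <- tibble::tibble(
    optimal = optimal,
    mean_ref_kpa = mean_ref,
    mean_alt_kpa = mean_alt,
    mean_reduction_kpa = red,
    mean_reduction_pct = pct,
    lower_bound_kpa = mean_ref - cfg$threshold_kpa,
    residual_area_cm2 = rroi_alt$total_area_cm2)
  class(out) <- c("qsf_reduction", class(out))
  out
}
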