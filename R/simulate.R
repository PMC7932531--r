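#' Synthetic foot pressure template
#'
#' The simulator represents the plantar pressure field as a baseline load
#' over a foot-shaped mask plus isotropic Gaussian high-pressure loci at
#' the clinically typical sites (heel, the five metatarsal heads, hallux).
#' Each locus has a centre, spatial SD, peak amplitude and a timing window
#' (as fractions of the stance phase) so that loading progresses heel to
#' forefoot during a step.
#'
#' @param grid A [regular_grid()]; default covers a 90 x 250 mm right foot
#'   at 5 mm cells.
#' @param loci Tibble with columns `name`, `x_mm`, `y_mm`, `sigma_mm`,
#'   `amplitude_kpa`, `t_on`, `t_off`; defaults emulate a high-risk
#'   neuropathic foot with several loci above 200 kPa.
#' @param baseline_kpa Broad foot-wide load amplitude; default 90 kPa.
#' @return An object of class `qsf_template`.
#' @export
foot_template <- function(grid = NULL, loci = NULL, baseline_kpa = 90) {
  grid <- grid %||% regular_grid(0, 0, 5, n_rows = 50, n_cols = 18)
  loci <- loci %||% default_loci()
  stopifnot(all(c("name", "x_mm", "y_mm", "sigma_mm", "amplitude_kpa",
                  "t_on", "t_off") %in% names(loci)),
            all(loci$amplitude_kpa >= 0), all(loci$sigma_mm > 0),
            baseline_kpa >= 0)
  structure(list(grid = grid, loci = tibble::as_tibble(loci),
                 baseline_kpa = baseline_kpa,
                 mask = foot_mask(grid)),
            class = "qsf_template")
}

# plausible high-risk neuropathic foot: heel, five metatarsal heads, hallux
default_loci <- function() {
  tibble::tibble(
    name = c("heel", "met1", "met2", "met3", "met4", "met5", "hallux"),
    x_mm = c(45, 22, 36, 50, 62, 74, 25),
    y_mm = c(40, 175, 180, 178, 172, 165, 225),
    sigma_mm = c(12, 9, 8, 8, 7, 7, 7),
    amplitude_kpa = c(380, 350, 420, 380, 300, 240, 320),
    t_on = c(0.00, 0.30, 0.30, 0.30, 0.30, 0.30, 0.55),
    t_off = c(0.55, 0.95, 0.95, 0.95, 0.95, 0.95, 1.00))
}

# foot-shaped boolean mask: heel disc + forefoot ellipse + connecting taper
foot_mask <- function(grid) {
  cells <- grid_cells(grid)
  heel <- ((cells$x_mm - 45)^2 / 35^2 + (cells$y_mm - 45)^2 / 45^2) <= 1
  fore <- ((cells$x_mm - 47)^2 / 42^2 + (cells$y_mm - 185)^2 / 60^2) <= 1
  mid <- cells$y_mm > 60 & cells$y_mm < 150 &
    cells$x_mm > 25 + 10 * sin(pi * (cells$y_mm - 60) / 90) &
    cells$x_mm < 83
  matrix(heel | fore | mid, grid$n_rows, grid$n_cols, byrow = TRUE)
}

#' Step-to-step variability model
#'
#' Gait is cyclic but never identical: successive stances differ in
#' duration and in foot-floor loading. The model uses per-step
#' multiplicative amplitude noise (CV), per-step spatial jitter of each
#' locus, Gaussian stance-duration variability and additive sensor noise.
#'
#' @param amplitude_cv Coefficient of variation of per-step locus
#'   amplitudes; default 0.1.
#' @param jitter_sd_mm SD of per-step locus displacement; default 2 mm.
#' @param stance_duration_mean_s,stance_duration_sd_s Stance duration
#'   distribution; defaults 0.7 and 0.05 s (comfortable-speed walking).
#' @param sensor_noise_sd_kpa Additive frame noise; default 0.
#' @return A list of class `qsf_variability`.
#' @export
variability_model <- function(amplitude_cv = 0.1, jitter_sd_mm = 2,
                              stance_duration_mean_s = 0.7,
                              stance_duration_sd_s = 0.05,
                              sensor_noise_sd_kpa = 0) {
  stopifnot(amplitude_cv >= 0, jitter_sd_mm >= 0,
            stance_duration_mean_s > 0, stance_duration_sd_s >= 0,
            sensor_noise_sd_kpa >= 0)
  structure(list(amplitude_cv = amplitude_cv, jitter_sd_mm = jitter_sd_mm,
                 stance_duration_mean_s = stance_duration_mean_s,
                 stance_duration_sd_s = stance_duration_sd_s,
                 sensor_noise_sd_kpa = sensor_noise_sd_kpa),
            class = "qsf_variability")
}

#' No step-to-step variability (deterministic gait)
#' @return A [variability_model()] with every noise term zero.
#' @export
no_variability <- function() {
  variability_model(amplitude_cv = 0, jitter_sd_mm = 0,
                    stance_duration_sd_s = 0, sensor_noise_sd_kpa = 0)
}

# Gaussian locus fields (cells x loci) for given centres
locus_fields <- function(template, x, y) {
  cells <- grid_cells(template$grid)
  L <- matrix(0, nrow(cells), nrow(template$loci))
  for (j in seq_len(nrow(template$loci))) {
    d2 <- (cells$x_mm - x[j])^2 + (cells$y_mm - y[j])^2
    L[, j] <- exp(-d2 / (2 * template$loci$sigma_mm[j]^2))
  }
  L
}

# trapezoidal temporal activation: ramp 30% of window, plateau 40%
trapezoid <- function(tau, on, off) {
  w <- (tau - on) / (off - on)
  out <- numeric(length(tau))
  inside <- w >= 0 & w <= 1
  out[inside] <- pmin(1, pmin(w[inside] / 0.3, (1 - w[inside]) / 0.3))
  out
}

#' Simulate an in-shoe walking recording
#'
#' Generates alternating stance and swing phases on the template grid.
#' Within each stance, loading progresses heel to forefoot following each
#' locus's timing window, scaled by per-step amplitude noise and spatially
#' jittered; the device range rule (floor 20 kPa -> 0, ceiling 600 kPa) is
#' applied after noise. The true stance windows are attached as attribute
#' `true_stances` for validation.
#'
#' @param template A [foot_template()].
#' @param var A [variability_model()].
#' @param n_steps Number of stance phases to simulate (>= 1).
#' @param sample_rate Hz; default 50.
#' @param swing_s Swing (no-contact) time between stances; default 0.45 s.
#' @param seed Optional integer seed for reproducibility.
#' @param meta Metadata list for the returned sequence.
#' @return A `qsf_grid_sequence`.
#' @export
simulate_walk <- function(template, var = variability_model(), n_steps,
                          sample_rate = 50, swing_s = 0.45, seed = NULL,
                          meta = list()) {
  stopifnot(inherits(template, "qsf_template"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- template$grid
  n_cells <- g$n_rows * g$n_cols
  n_loci <- nrow(template$loci)
  swing_frames <- max(1L, round(swing_s * sample_rate))
  base_field <- as.vector(t(template$mask)) * template$baseline_kpa

  blocks <- list()
  true_start <- integer(n_steps); true_end <- integer(n_steps)
  cursor <- 0L
  for (s in seq_len(n_steps)) {
    blocks[[length(blocks) + 1L]] <- matrix(0, swing_frames, n_cells)
    cursor <- cursor + swing_frames
    dur <- var$stance_duration_mean_s +
      if (var$stance_duration_sd_s > 0) stats::rnorm(1, 0, var$stance_duration_sd_s) else 0
    dur <- max(0.3, dur)
    nf <- max(5L, round(dur * sample_rate))
    amp <- template$loci$amplitude_kpa *
      if (var$amplitude_cv > 0) pmax(0.05, stats::rnorm(n_loci, 1, var$amplitude_cv)) else 1
    jx <- template$loci$x_mm +
      if (var$jitter_sd_mm > 0) stats::rnorm(n_loci, 0, var$jitter_sd_mm) else 0
    jy <- template$loci$y_mm +
      if (var$jitter_sd_mm > 0) stats::rnorm(n_loci, 0, var$jitter_sd_mm) else 0
    tau <- (seq_len(nf) - 0.5) / nf
    L <- locus_fields(template, jx, jy)
    W <- t(vapply(seq_len(n_loci), function(j) {
      amp[j] * trapezoid(tau, template$loci$t_on[j], template$loci$t_off[j])
    }, numeric(nf)))
    Fr <- t(L %*% W)
    base_amp <- if (var$amplitude_cv > 0) pmax(0.05, stats::rnorm(1, 1, var$amplitude_cv)) else 1
    Fr <- Fr + outer(trapezoid(tau, 0.02, 0.98), base_field * base_amp)
    if (var$sensor_noise_sd_kpa > 0) {
      Fr <- Fr + matrix(stats::rnorm(length(Fr), 0, var$sensor_noise_sd_kpa),
                        nrow(Fr), ncol(Fr))
    }
    Fr <- clip_pressure_range(Fr)
    attr(Fr, "n_clipped") <- NULL
    blocks[[length(blocks) + 1L]] <- Fr
    true_start[s] <- cursor + 1L
    true_end[s] <- cursor + nf + 1L
    cursor <- cursor + nf
  }
  blocks[[length(blocks) + 1L]] <- matrix(0, swing_frames, n_cells)
  frames <- do.call(rbind, blocks)
  seq <- grid_sequence(g, frames, sample_rate = sample_rate, meta = meta)
  attr(seq, "true_stances") <- tibble::tibble(
    step_index = seq_len(n_steps), start_frame = true_start, end_frame = true_end)
  seq
}

#' Apply an offloading intervention to a template
#'
#' Emulates the effect of a custom insole: each locus amplitude is scaled
#' by `1 - reduction`, and a fraction of the total removed peak load can
#' be rerouted to a midfoot/arch locus (insoles redistribute load, they do
#' not destroy it).
#'
#' @param template A [foot_template()].
#' @param reduction Either a single fraction in `[0, 1]` applied to every
#'   locus, or a named vector keyed by locus name.
#' @param redistribute_fraction Fraction of removed amplitude added to the
#'   arch locus; default 0.
#' @param arch Arch locus description used when the template lacks one:
#'   list with `x_mm`, `y_mm`, `sigma_mm`.
#' @return A new `qsf_template`.
#' @export
apply_offload <- function(template, reduction, redistribute_fraction = 0,
                          arch = list(x_mm = 55, y_mm = 110, sigma_mm = 15)) {
  stopifnot(inherits(template, "qsf_template"),
            all(reduction >= 0), all(reduction <= 1),
            redistribute_fraction >= 0, redistribute_fraction <= 1)
  loci <- template$loci
  r <- if (is.null(names(reduction))) {
    rep(reduction, length.out = nrow(loci))
  } else {
    out <- rep(0, nrow(loci))
    idx <- match(names(reduction), loci$name)
    if (anyNA(idx)) {
      abort(paste0("unknown locus name(s): ",
                   paste(names(reduction)[is.na(idx)], collapse = ", ")),
            class = "qsf_sim_error")
    }
    out[idx] <- reduction
    out
  }
  removed <- sum(loci$amplitude_kpa * r)
  loci$amplitude_kpa <- loci$amplitude_kpa * (1 - r)
  if (redistribute_fraction > 0 && removed > 0) {
    if ("arch" %in% loci$name) {
      loci$amplitude_kpa[loci$name == "arch"] <-
        loci$amplitude_kpa[loci$name == "arch"] + redistribute_fraction * removed
    } else {
      loci <- dplyr::bind_rows(loci, tibble::tibble(
        name = "arch", x_mm = arch$x_mm, y_mm = arch$y_mm,
        sigma_mm = arch$sigma_mm,
        amplitude_kpa = redistribute_fraction * removed,
        t_on = 0.2, t_off = 0.8))
    }
  }
  foot_template(template$grid, loci, template$baseline_kpa)
}

#' Expected (noiseless) peak pressure map of a template
#'
#' The per-cell peak realised by a deterministic stance of the template at
#' the mean stance duration -- the simulator's ground truth for the MPPM.
#'
#' @param template A [foot_template()].
#' @param var A [variability_model()] (only the mean stance duration is
#'   used).
#' @param sample_rate Hz.
#' @return Matrix `n_rows` x `n_cols` of expected peak pressures (kPa).
#' @export
expected_peak_map <- function(template, var = variability_model(),
                              sample_rate = 50) {
  g <- template$grid
  nf <- max(5L, round(var$stance_duration_mean_s * sample_rate))
  tau <- (seq_len(nf) - 0.5) / nf
  L <- locus_fields(template, template$loci$x_mm, template$loci$y_mm)
  W <- t(vapply(seq_len(nrow(template$loci)), function(j) {
    template$loci$amplitude_kpa[j] *
      trapezoid(tau, template$loci$t_on[j], template$loci$t_off[j])
  }, numeric(nf)))
  Fr <- t(L %*% W) + outer(trapezoid(tau, 0.02, 0.98),
                           as.vector(t(template$mask)) * template$baseline_kpa)
  Fr <- clip_pressure_range(Fr)
  v <- apply(Fr, 2L, max)
  matrix(v, g$n_rows, g$n_cols, byrow = TRUE)
}

#' Asymptotic ground-truth R-ROI of a template
#'
#' The risk mask the pipeline would converge to with infinitely many
#' steps: the per-cell test statistics concentrate at the expected peak
#' mean, so the statistical rules all reduce to `mean >= threshold`; the
#' dispersion-band rule keeps its SD allowance, approximated as
#' `amplitude_cv * mean`.
#'
#' @param template A [foot_template()].
#' @param var A [variability_model()].
#' @param cfg An [rroi_config()].
#' @param sample_rate Hz.
#' @return A `qsf_rroi`.
#' @export
ground_truth_rroi <- function(template, var = variability_model(),
                              cfg = rroi_config(), sample_rate = 50) {
  E <- expected_peak_map(template, var, sample_rate)
  mask <- if (cfg$rule == "dispersion_band") {
    E >= cfg$threshold_kpa |
      (cfg$threshold_kpa - E) <= qnorm(1 - cfg$alpha) * var$amplitude_cv * E
  } else {
    E >= cfg$threshold_kpa
  }
  labels <- label_components(mask, cfg$connectivity)
  structure(list(grid = template$grid, in_rroi = mask, cluster_labels = labels,
                 n_clusters = max(labels), cfg = cfg,
                 total_area_cm2 = sum(mask) * cell_area_cm2(template$grid)),
            class = "qsf_rroi")
}

#' Synthetic 99-sensor insole layout
#'
#' A pedar-like rectilinear lattice of 9 columns x 11 rows = 99 sensors of
#' unequal sizes (finer under the forefoot), covering 90 x 250 mm.
#'
#' @param side `"left"` or `"right"`.
#' @return A [sensor_layout()].
#' @export
synthetic_layout_99 <- function(side = "right") {
  xb <- c(0, 11, 22, 33, 44, 55, 66, 74, 82, 90)
  yb <- c(0, 28, 56, 84, 112, 140, 160, 178, 196, 214, 232, 250)
  grid <- expand.grid(col = seq_len(length(xb) - 1L),
                      row = seq_len(length(yb) - 1L))
  sensor_layout(tibble::tibble(
    sensor_id = seq_len(nrow(grid)),
    x_min_mm = xb[grid$col], x_max_mm = xb[grid$col + 1L],
    y_min_mm = yb[grid$row], y_max_mm = yb[grid$row + 1L]),
    side = side)
}

#' Downsample a simulated grid sequence onto a sensor layout
#'
#' Converts simulated grid frames into a sensor-level recording by
#' area-averaging each frame over every sensor rectangle -- the synthetic
#' counterpart of a raw in-shoe export, useful for exercising the full
#' read -> resample -> analyse pipeline.
#'
#' @param seq A `qsf_grid_sequence` (e.g. from [simulate_walk()]).
#' @param layout A [sensor_layout()]; default [synthetic_layout_99()].
#' @return A `qsf_recording`.
#' @export
as_sensor_recording <- function(seq, layout = synthetic_layout_99()) {
  stopifnot(inherits(seq, "qsf_grid_sequence"))
  W <- overlap_weights(layout, seq$grid)  # cells x sensors
  cov <- colSums(W)
  if (any(cov == 0)) {
    abort("layout has sensors with no grid support", class = "qsf_sim_error")
  }
  sensor_vals <- seq$frames %*% W %*% diag(1 / cov, length(cov))
  sensor_vals <- clip_pressure_range(sensor_vals)
  attr(sensor_vals, "n_clipped") <- NULL
  colnames(sensor_vals) <- sprintf("s%03d", layout$sensor_id)
  new_pressure_recording(layout, sensor_vals, seq$sample_rate,
                         meta = c(seq$meta,
                                  list(t_s = seq$timestamps,
                                       side = attr(layout, "side"))))
}
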