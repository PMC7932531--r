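#' Stance-detection configuration
#'
#' A frame is "in contact" when at least `min_contact_cells` grid cells read
#' at or above `contact_pressure_floor`. Maximal runs of contact frames
#' whose duration lies in `[min_stance_frames, max_stance_frames]` become
#' stance phases; the first and last `trim_steps_per_pass` stances of each
#' walking pass are dropped so only mid-walk, steady-speed foot contacts
#' enter the analysis.
#'
#' @param contact_pressure_floor kPa; default 20, the device floor.
#' @param min_contact_cells Cells that must exceed the floor; default 4.
#' @param min_stance_frames,max_stance_frames Admissible stance durations in
#'   frames; defaults 10 and 120 (0.2--2.4 s at 50 Hz).
#' @param trim_steps_per_pass Gait-initiation/termination steps dropped at
#'   each end of every pass; default 1.
#' @return A list of class `qsf_stance_config`.
#' @export
stance_config <- function(contact_pressure_floor = 20, min_contact_cells = 4,
                          min_stance_frames = 10, max_stance_frames = 120,
                          trim_steps_per_pass = 1) {
  stopifnot(contact_pressure_floor > 0, min_contact_cells > 0,
            min_stance_frames > 0, max_stance_frames > min_stance_frames,
            trim_steps_per_pass >= 0)
  structure(list(contact_pressure_floor = contact_pressure_floor,
                 min_contact_cells = min_contact_cells,
                 min_stance_frames = min_stance_frames,
                 max_stance_frames = max_stance_frames,
                 trim_steps_per_pass = trim_steps_per_pass),
            class = "qsf_stance_config")
}

#' Segment a grid sequence into stance phases
#'
#' @param seq A `qsf_grid_sequence`.
#' @param cfg A [stance_config()].
#' @param passes Optional integer vector (one per frame) giving pass
#'   membership when the recording concatenates several walkway passes;
#'   trimming is applied per pass. Default: the whole recording is one pass.
#' @return Tibble with `step_index`, `start_frame`, `end_frame` (half-open
#'   `[start, end)`), possibly empty.
#' @export
detect_stances <- function(seq, cfg = stance_config(), passes = NULL) {
  stopifnot(inherits(seq, "qsf_grid_sequence"))
  nf <- n_frames(seq)
  contact <- rowSums(seq$frames >= cfg$contact_pressure_floor) >= cfg$min_contact_cells
  passes <- passes %||% rep(1L, nf)
  if (length(passes) != nf) {
    abort("passes must have one entry per frame", class = "qsf_stance_error")
  }
  out <- list()
  for (p in unique(passes)) {
    idx <- which(passes == p)
    r <- rle(contact[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= cfg$min_stance_frames &
      r$lengths <= cfg$max_stance_frames
    st <- idx[starts[keep]]
    en <- idx[ends[keep]] + 1L
    k <- cfg$trim_steps_per_pass
    if (length(st) > 2 * k) {
      sel <- seq.int(k + 1L, length(st) - k)
      out[[length(out) + 1L]] <- tibble::tibble(start_frame = st[sel],
                                                end_frame = en[sel])
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(start_frame = integer(), end_frame = integer())
  }
  res <- dplyr::arrange(res, .data$start_frame)
  tibble::tibble(step_index = seq_len(nrow(res)), res)
}

#' Per-stance peak pressure map
#'
#' The peak pressure map of a stance assigns to each grid cell the highest
#' pressure recorded in that cell over the stance's frames.
#'
#' @param seq A `qsf_grid_sequence`.
#' @param start_frame,end_frame Half-open frame range `[start, end)`.
#' @param step_index Step label carried on the result.
#' @return An object of class `qsf_peak_map`: list with `grid`, `values`
#'   (`n_rows` x `n_cols` matrix, kPa) and `step_index`.
#' @export
peak_pressure_map <- function(seq, start_frame, end_frame, step_index = NA_integer_) {
  stopifnot(inherits(seq, "qsf_grid_sequence"))
  if (start_frame < 1 || end_frame > n_frames(seq) + 1L || end_frame <= start_frame) {
    abort("stance phase out of sequence bounds", class = "qsf_stance_error")
  }
  block <- seq$frames[start_frame:(end_frame - 1L), , drop = FALSE]
  v <- apply(block, 2L, max)
  structure(list(grid = seq$grid,
                 values = matrix(v, seq$grid$n_rows, seq$grid$n_cols, byrow = TRUE),
                 step_index = step_index),
            class = "qsf_peak_map")
}

#' Peak maps for every detected stance
#'
#' @param seq A `qsf_grid_sequence`.
#' @param stances Tibble from [detect_stances()]; detected with defaults
#'   when omitted.
#' @param cfg A [stance_config()] used when `stances` is omitted.
#' @return List of `qsf_peak_map`.
#' @export
peak_maps <- function(seq, stances = NULL, cfg = stance_config()) {
  stances <- stances %||% detect_stances(seq, cfg)
  purrr::pmap(stances, function(step_index, start_frame, end_frame) {
    peak_pressure_map(seq, start_frame, end_frame, step_index)
  })
}

#' Mean peak pressure map (MPPM)
#'
#' Averages a sequence of per-stance peak maps cell by cell, keeping the
#' per-cell sample SD (n - 1 denominator, as consumed by the downstream
#' t-tests). The method's power analysis asks for at least `min_n` stances
#' (24 by default, the paired-test requirement); fewer stances produce a
#' warning, not an error, so exploratory runs remain possible.
#'
#' @param maps List of `qsf_peak_map` on a common grid.
#' @param min_n Advisory minimum number of stances; default 24.
#' @return An object of class `qsf_mppm`: list with `grid`, `mean`, `sd`
#'   (matrices, kPa) and `n`.
#' @export
mean_peak_map <- function(maps, min_n = 24) {
  if (length(maps) < 2L) {
    abort("need at least 2 peak maps to form an MPPM", class = "qsf_mppm_error")
  }
  g <- maps[[1L]]$grid
  for (m in maps[-1L]) {
    if (!same_grid(m$grid, g)) {
      abort("peak maps are on different grids", class = "qsf_mppm_error")
    }
  }
  n <- length(maps)
  if (n < min_n) {
    warn(sprintf(paste("MPPM built from %d stances; the paired-test power",
                       "analysis requires at least %d"), n, min_n))
  }
  X <- vapply(maps, function(m) as.vector(m$values), numeric(g$n_rows * g$n_cols))
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, sd)
  structure(list(grid = g,
                 mean = matrix(mu, g$n_rows, g$n_cols),
                 sd = matrix(sdv, g$n_rows, g$n_cols),
                 n = n),
            class = "qsf_mppm")
}

#' @export
print.qsf_mppm <- function(x, ...) {
  cat(sprintf("<qsf_mppm> mean peak pressure map over %d stances, %d x %d cells\n",
              x$n, x$grid$n_rows, x$grid$n_cols))
  cat(sprintf("  max mean peak: %.1f kPa\n", max(x$mean)))
  invisible(x)
}

#' Tidy a peak map or MPPM into a long tibble
#' @param x A `qsf_peak_map` or `qsf_mppm`.
#' @param ... Unused.
#' @return One row per cell with coordinates and values.
#' @export
tidy.qsf_peak_map <- function(x, ...) {
  dplyr::bind_cols(grid_cells(x$grid),
                   tibble::tibble(peak_kpa = as.vector(t(x$values)),
                                  step_index = x$step_index))
}

#' @rdname tidy.qsf_peak_map
#' @export
tidy.qsf_mppm <- function(x, ...) {
  dplyr::bind_cols(grid_cells(x$grid),
                   tibble::tibble(mean_kpa = as.vector(t(x$mean)),
                                  sd_kpa = as.vector(t(x$sd)),
                                  n = x$n))
}
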