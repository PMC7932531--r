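#' Build the regular grid covering a sensor layout
#'
#' The grid's bounding box covers the union of the sensor rectangles, with
#' the origin snapped down to a multiple of `cell_mm` so that cell
#' boundaries are stable across layouts.
#'
#' @param layout A [sensor_layout()].
#' @param cell_mm Cell edge length in mm (default 5).
#' @return A [regular_grid()].
#' @export
make_grid_for_layout <- function(layout, cell_mm = 5) {
  if (cell_mm <= 0) abort("cell_mm must be positive", class = "qsf_grid_error")
  x_min <- min(layout$x_min_mm); x_max <- max(layout$x_max_mm)
  y_min <- min(layout$y_min_mm); y_max <- max(layout$y_max_mm)
  x0 <- floor(x_min / cell_mm) * cell_mm
  y0 <- floor(y_min / cell_mm) * cell_mm
  n_cols <- ceiling((x_max - x0) / cell_mm - 1e-9)
  n_rows <- ceiling((y_max - y0) / cell_mm - 1e-9)
  regular_grid(x0, y0, cell_mm, n_rows, n_cols)
}

# sparse-ish overlap weight matrix: cells (row-major) x sensors, entries in mm^2
overlap_weights <- function(layout, grid) {
  cells <- grid_cells(grid)
  cl <- grid$x0 + (cells$col - 1) * grid$cell_mm
  cb <- grid$y0 + (cells$row - 1) * grid$cell_mm
  n_cells <- nrow(cells); n_sens <- nrow(layout)
  W <- matrix(0, n_cells, n_sens)
  for (s in seq_len(n_sens)) {
    ox <- pmin(cl + grid$cell_mm, layout$x_max_mm[s]) - pmax(cl, layout$x_min_mm[s])
    oy <- pmin(cb + grid$cell_mm, layout$y_max_mm[s]) - pmax(cb, layout$y_min_mm[s])
    w <- pmax(ox, 0) * pmax(oy, 0)
    W[, s] <- w
  }
  W
}

#' Resample one sensor frame onto a regular grid
#'
#' Two schemes are offered for turning irregular, unequal-size sensor
#' readings into regular cells:
#' \describe{
#'   \item{`area_weighted`}{each cell value is the overlap-area-weighted
#'     mean of the sensors intersecting it. Constant fields are preserved
#'     and total force (pressure x area) is conserved where sensors tile
#'     the grid.}
#'   \item{`centroid_bilinear`}{bilinear interpolation of sensor-centroid
#'     values, defined for layouts whose centroids form a complete
#'     rectilinear lattice (true of pedar-like insoles); clamped to >= 0.}
#' }
#' Cells covered by no sensor receive `outside_value` (0 by default, so
#' downstream max/mean semantics stay total).
#'
#' @param pressures Numeric vector, one value per layout sensor (kPa).
#' @param layout A [sensor_layout()].
#' @param grid A [regular_grid()].
#' @param method `"area_weighted"` (default) or `"centroid_bilinear"`.
#' @param outside_value Fill for cells with no sensor support.
#' @param weights Optional precomputed overlap weight matrix (internal
#'   fast path for sequences).
#' @return `n_rows` x `n_cols` matrix of resampled pressures.
#' @export
resample_frame <- function(pressures, layout, grid,
                           method = c("area_weighted", "centroid_bilinear"),
                           outside_value = 0, weights = NULL) {
  method <- match.arg(method)
  if (length(pressures) != nrow(layout)) {
    abort(sprintf("frame has %d values but layout has %d sensors",
                  length(pressures), nrow(layout)),
          class = "qsf_resample_error")
  }
  if (method == "area_weighted") {
    W <- weights %||% overlap_weights(layout, grid)
    tot <- W %*% pressures
    cov <- rowSums(W)
    v <- ifelse(cov > 0, tot / cov, outside_value)
  } else {
    v <- bilinear_centroid(pressures, layout, grid, outside_value)
  }
  matrix(v, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

# bilinear interpolation on the rectilinear lattice of sensor centroids
bilinear_centroid <- function(pressures, layout, grid, outside_value) {
  cx <- (layout$x_min_mm + layout$x_max_mm) / 2
  cy <- (layout$y_min_mm + layout$y_max_mm) / 2
  xs <- sort(unique(round(cx, 6))); ys <- sort(unique(round(cy, 6)))
  if (length(xs) * length(ys) != nrow(layout)) {
    abort(paste("centroid_bilinear requires sensor centroids on a complete",
                "rectilinear lattice; use method = 'area_weighted'"),
          class = "qsf_resample_error")
  }
  Z <- matrix(NA_real_, length(ys), length(xs))
  Z[cbind(match(round(cy, 6), ys), match(round(cx, 6), xs))] <- pressures
  cells <- grid_cells(grid)
  inside <- cells$x_mm >= xs[1] & cells$x_mm <= xs[length(xs)] &
    cells$y_mm >= ys[1] & cells$y_mm <= ys[length(ys)]
  v <- rep(outside_value, nrow(cells))
  if (any(inside)) {
    if (!requireNamespace("pracma", quietly = TRUE)) {
      abort("centroid_bilinear requires the pracma package",
            class = "qsf_resample_error")
    }
    v[inside] <- pracma::interp2(xs, ys, Z, cells$x_mm[inside],
                                 cells$y_mm[inside], method = "linear")
    v[inside] <- pmax(v[inside], 0)
  }
  v
}

#' Resample a sensor recording onto a regular grid
#'
#' Frame-wise application of [resample_frame()]; timestamps and metadata
#' are preserved.
#'
#' @param rec A `qsf_recording`.
#' @param grid A [regular_grid()]; default [make_grid_for_layout()] at 5 mm.
#' @inheritParams resample_frame
#' @return A `qsf_grid_sequence`.
#' @export
resample_recording <- function(rec, grid = NULL,
                               method = c("area_weighted", "centroid_bilinear"),
                               outside_value = 0) {
  stopifnot(inherits(rec, "qsf_recording"))
  method <- match.arg(method)
  if (!nrow(rec$frames)) abort("empty recording", class = "qsf_resample_error")
  grid <- grid %||% make_grid_for_layout(rec$layout)
  W <- if (method == "area_weighted") overlap_weights(rec$layout, grid)
  frames <- t(vapply(seq_len(nrow(rec$frames)), function(i) {
    as.vector(t(resample_frame(rec$frames[i, ], rec$layout, grid,
                               method = method, outside_value = outside_value,
                               weights = W)))
  }, numeric(grid$n_rows * grid$n_cols)))
  grid_sequence(grid, frames,
                timestamps = rec$meta$t_s %||% NULL,
                sample_rate = rec$sample_rate,
                meta = rec$meta[intersect(names(rec$meta),
                                          c("subject", "side", "condition"))])
}
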