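# Shared fixtures, all generated in code.

# tiny two-sensor layout: two 10x10 mm squares side by side
tiny_layout <- function(side = "left") {
  sensor_layout(data.frame(
    sensor_id = 1:2,
    x_min_mm = c(0, 10), y_min_mm = 0,
    x_max_mm = c(10, 20), y_max_mm = 10), side = side)
}

# write a PressureCSV file + layout file into dir; returns the csv path
write_tiny_pressure_csv <- function(dir, values, sample_rate = 50,
                                    side = "left") {
  layout_path <- file.path(dir, "layout.csv")
  write_sensor_layout(tiny_layout(side), layout_path)
  csv <- file.path(dir, "rec.csv")
  n <- nrow(values)
  lines <- c("# layout=layout.csv",
             sprintf("# sample_rate_hz=%g", sample_rate),
             sprintf("# side=%s", side),
             "t_s,s001,s002",
             vapply(seq_len(n), function(i) {
               sprintf("%g,%g,%g", (i - 1) / sample_rate,
                       values[i, 1], values[i, 2])
             }, ""))
  writeLines(lines, csv)
  csv
}

# layout of n x m equal square sensors tiling [0, m*w] x [0, n*w]
tiled_layout <- function(n_rows, n_cols, w = 10) {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  sensor_layout(data.frame(
    sensor_id = seq_len(nrow(grid)),
    x_min_mm = (grid$col - 1) * w, x_max_mm = grid$col * w,
    y_min_mm = (grid$row - 1) * w, y_max_mm = grid$row * w),
    side = "right")
}

# random irregular-but-tiling layout: random x/y breaks over a rectangle
random_tiled_layout <- function(seed, extent = c(60, 100)) {
  set.seed(seed)
  xb <- sort(c(0, extent[1], runif(3, 5, extent[1] - 5)))
  yb <- sort(c(0, extent[2], runif(4, 5, extent[2] - 5)))
  grid <- expand.grid(col = seq_len(length(xb) - 1), row = seq_len(length(yb) - 1))
  sensor_layout(data.frame(
    sensor_id = seq_len(nrow(grid)),
    x_min_mm = xb[grid$col], x_max_mm = xb[grid$col + 1],
    y_min_mm = yb[grid$row], y_max_mm = yb[grid$row + 1]),
    side = "left")
}

# grid sequence with explicit frame matrices
seq_from_matrices <- function(mats, cell_mm = 5, sample_rate = 50) {
  g <- regular_grid(0, 0, cell_mm, nrow(mats[[1]]), ncol(mats[[1]]))
  grid_sequence(g, mats, sample_rate = sample_rate)
}

# square-wave loading: n_steps contacts of `on` frames separated by `off`
# zero frames, on a 4x4 grid with `n_cells_loaded` cells at `level` kPa
square_wave_seq <- function(n_steps, on = 20, off = 10, level = 150,
                            n_cells_loaded = 6) {
  m_on <- matrix(0, 4, 4)
  m_on[seq_len(n_cells_loaded)] <- level
  m_off <- matrix(0, 4, 4)
  mats <- list(m_off)
  for (s in seq_len(n_steps)) {
    mats <- c(mats, replicate(on, m_on, simplify = FALSE),
              replicate(off, m_off, simplify = FALSE))
  }
  seq_from_matrices(mats)
}

# peak-map object on a small grid directly from a matrix
peak_from_matrix <- function(m, step_index = 1L, cell_mm = 5) {
  seqn <- seq_from_matrices(list(m), cell_mm = cell_mm)
  peak_pressure_map(seqn, 1, 2, step_index)
}

# mppm directly from mean / sd matrices (bypasses stance machinery)
mppm_from_matrices <- function(mean, sd, n, cell_mm = 5) {
  g <- regular_grid(0, 0, cell_mm, nrow(mean), ncol(mean))
  structure(list(grid = g, mean = mean, sd = sd, n = n), class = "qsf_mppm")
}

# synthetic S1-style cohort area table: 60 feet x 3 conditions emulating
# strong offloading by both custom insoles with many complete removals
synthetic_cohort_table <- function(seed = 20260921) {
  set.seed(seed)
  n <- 60
  fi <- pmax(0, rnorm(n, mean = 20, sd = 12))
  tcci <- pmax(0, fi * runif(n, 0.05, 0.7) - runif(n, 0, 4))
  cad <- pmax(0, fi * runif(n, 0.02, 0.6) - runif(n, 0, 5))
  as_area_table(tibble::tibble(
    subject = rep(sprintf("S%02d", 1:30), each = 2),
    side = rep(c("left", "right"), 30),
    FI = round(fi, 2), TCCI = round(tcci, 2), CADCAM = round(cad, 2)))
}
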