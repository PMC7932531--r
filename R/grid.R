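#' Regular analysis grids
#'
#' After resampling, every cell of the pressure map is a square of
#' `cell_mm` x `cell_mm` (5 mm by default, i.e. 0.25 cm^2 per cell) in the
#' same foot-local millimetre frame as the sensor layout.
#'
#' @param x0,y0 Grid origin (lower-left corner), mm.
#' @param cell_mm Cell edge length, mm.
#' @param n_rows,n_cols Grid dimensions. Rows index y (row 1 at `y0`),
#'   columns index x.
#' @return An object of class `qsf_grid`.
#' @export
regular_grid <- function(x0, y0, cell_mm = 5, n_rows, n_cols) {
  if (cell_mm <= 0) abort("cell_mm must be positive", class = "qsf_grid_error")
  if (n_rows < 1 || n_cols < 1) {
    abort("grid must have at least one row and column", class = "qsf_grid_error")
  }
  structure(list(x0 = x0, y0 = y0, cell_mm = cell_mm,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "qsf_grid")
}

#' @export
print.qsf_grid <- function(x, ...) {
  cat(sprintf("<qsf_grid> %d x %d cells of %g mm, origin (%g, %g) mm\n",
              x$n_rows, x$n_cols, x$cell_mm, x$x0, x$y0))
  invisible(x)
}

#' Cell area of a grid in cm^2
#' @param grid A [regular_grid()].
#' @return Cell area in cm^2 (0.25 at the default 5 mm).
#' @export
cell_area_cm2 <- function(grid) (grid$cell_mm / 10)^2

#' Cell centre coordinates of a grid
#' @param grid A [regular_grid()].
#' @return Tibble `row`, `col`, `x_mm`, `y_mm` in row-major cell order.
#' @export
grid_cells <- function(grid) {
  rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    row = rows, col = cols,
    x_mm = grid$x0 + (cols - 0.5) * grid$cell_mm,
    y_mm = grid$y0 + (rows - 0.5) * grid$cell_mm)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

new_grid_sequence <- function(grid, frames, timestamps, sample_rate, meta = list()) {
  structure(list(grid = grid, frames = frames, timestamps = timestamps,
                 sample_rate = sample_rate, meta = meta),
            class = "qsf_grid_sequence")
}

#' Construct a grid-frame sequence
#'
#' A grid sequence holds time-ordered resampled pressure frames on a single
#' regular grid. Frames are stored as a matrix with one row per frame and
#' one column per cell in row-major cell order.
#'
#' @param grid A [regular_grid()].
#' @param frames Numeric matrix, frames x cells (row-major cells), kPa; or a
#'   list of `n_rows` x `n_cols` matrices.
#' @param timestamps Strictly increasing frame times in seconds; default
#'   regular sampling at `sample_rate`.
#' @param sample_rate Hz.
#' @param meta Named list (subject, side, condition, ...).
#' @return An object of class `qsf_grid_sequence`.
#' @export
grid_sequence <- function(grid, frames, timestamps = NULL, sample_rate = 50,
                          meta = list()) {
  if (is.list(frames) && !is.matrix(frames)) {
    if (!length(frames)) abort("empty sequence", class = "qsf_grid_error")
    frames <- do.call(rbind, lapply(frames, function(m) {
      if (!all(dim(m) == c(grid$n_rows, grid$n_cols))) {
        abort("frame shape does not match grid", class = "qsf_grid_error")
      }
      as.vector(t(m))  # row-major
    }))
  }
  if (!is.matrix(frames) || nrow(frames) < 1L) {
    abort("empty sequence", class = "qsf_grid_error")
  }
  if (ncol(frames) != grid$n_rows * grid$n_cols) {
    abort("frame shape does not match grid", class = "qsf_grid_error")
  }
  if (any(frames < 0)) abort("pressures must be >= 0", class = "qsf_grid_error")
  if (is.null(timestamps)) {
    timestamps <- (seq_len(nrow(frames)) - 1) / sample_rate
  }
  if (length(timestamps) != nrow(frames) || is.unsorted(timestamps, strictly = TRUE)) {
    abort("timestamps must be strictly increasing, one per frame",
          class = "qsf_grid_error")
  }
  new_grid_sequence(grid, unname(frames), timestamps, sample_rate, meta)
}

#' Number of frames in a grid sequence
#' @param seq A `qsf_grid_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) nrow(seq$frames)

#' Extract one frame of a grid sequence as a matrix
#' @param seq A `qsf_grid_sequence`.
#' @param i Frame index.
#' @return `n_rows` x `n_cols` matrix of pressures (kPa).
#' @export
frame_matrix <- function(seq, i) {
  matrix(seq$frames[i, ], nrow = seq$grid$n_rows, ncol = seq$grid$n_cols,
         byrow = TRUE)
}

#' @export
print.qsf_grid_sequence <- function(x, ...) {
  cat(sprintf("<qsf_grid_sequence> %d frames on %d x %d grid (%g mm) @ %g Hz\n",
              n_frames(x), x$grid$n_rows, x$grid$n_cols, x$grid$cell_mm,
              x$sample_rate))
  invisible(x)
}

#' Write / read a grid sequence as plain text
#'
#' The file is a CSV with a `# grid=x0,y0,cell_mm,n_rows,n_cols` header
#' (plus `# sample_rate_hz=` and optional meta lines), a `t_s,c0001,...`
#' column header, and one row per frame with cells in row-major order.
#' Values round-trip bit-exactly.
#'
#' @param seq A `qsf_grid_sequence`.
#' @param path File path.
#' @return `write_grid_sequence()` returns `path` invisibly;
#'   `read_grid_sequence()` returns the `qsf_grid_sequence`.
#' @export
write_grid_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "qsf_grid_sequence"))
  if (!n_frames(seq)) abort("empty sequence", class = "qsf_grid_error")
  g <- seq$grid
  hdr <- c(sprintf("# grid=%s,%s,%s,%d,%d", fmt_num(g$x0), fmt_num(g$y0),
                   fmt_num(g$cell_mm), g$n_rows, g$n_cols),
           sprintf("# sample_rate_hz=%s", fmt_num(seq$sample_rate)))
  for (k in intersect(c("subject", "side", "condition"), names(seq$meta))) {
    if (!is.na(seq$meta[[k]])) hdr <- c(hdr, sprintf("# %s=%s", k, seq$meta[[k]]))
  }
  header_row <- paste(c("t_s", sprintf("c%04d", seq_len(ncol(seq$frames)))),
                      collapse = ",")
  rows <- vapply(seq_len(n_frames(seq)), function(i) {
    paste(c(fmt_num(seq$timestamps[i]), fmt_num(seq$frames[i, ])), collapse = ",")
  }, "")
  writeLines(c(hdr, header_row, rows), path)
  invisible(path)
}

#' @rdname write_grid_sequence
#' @export
read_grid_sequence <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  hdr <- lines[is_comment]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  meta <- as.list(setNames(trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), "")),
                           trimws(vapply(kv, `[`, "", 1L))))
  if (is.null(meta$grid)) {
    abort("format error: missing '# grid=' header", class = "qsf_parse_error")
  }
  gp <- suppressWarnings(as.numeric(strsplit(meta$grid, ",")[[1L]]))
  if (length(gp) != 5L || anyNA(gp)) {
    abort("format error: malformed '# grid=' header", class = "qsf_parse_error")
  }
  grid <- regular_grid(gp[1L], gp[2L], gp[3L], gp[4L], gp[5L])
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L) abort("empty sequence", class = "qsf_parse_error")
  parts <- strsplit(body[-1L], ",", fixed = TRUE)
  n_cells <- grid$n_rows * grid$n_cols
  if (any(lengths(parts) != n_cells + 1L)) {
    abort("format error: frame width does not match grid shape",
          class = "qsf_parse_error")
  }
  num <- suppressWarnings(matrix(as.numeric(unlist(parts, use.names = FALSE)),
                                 nrow = length(parts), byrow = TRUE))
  if (anyNA(num)) abort("format error: non-numeric value", class = "qsf_parse_error")
  grid_sequence(grid, num[, -1L, drop = FALSE], timestamps = num[, 1L],
                sample_rate = suppressWarnings(as.numeric(meta$sample_rate_hz %||% "50")),
                meta = meta[intersect(names(meta), c("subject", "side", "condition"))])
}

#' Tidy a grid sequence into a long tibble
#'
#' @param x A `qsf_grid_sequence`.
#' @param ... Unused.
#' @return Tibble with `frame`, `t_s`, `row`, `col`, `x_mm`, `y_mm`,
#'   `pressure_kpa`.
#' @export
tidy.qsf_grid_sequence <- function(x, ...) {
  cells <- grid_cells(x$grid)
  nf <- n_frames(x)
  dplyr::bind_cols(
    tibble::tibble(frame = rep(seq_len(nf), each = nrow(cells)),
                   t_s = rep(x$timestamps, each = nrow(cells))),
    cells[rep(seq_len(nrow(cells)), times = nf), ],
    tibble::tibble(pressure_kpa = as.vector(t(x$frames))))
}
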