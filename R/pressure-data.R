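#' Sensor layouts for in-shoe pressure insoles
#'
#' An insole layout is a set of axis-aligned rectangular sensors in
#' foot-local millimetre coordinates (origin at the posterior-lateral heel
#' corner, y increasing toward the toes). Capacitive in-shoe insoles use
#' sensors of unequal size depending on their position, so each sensor
#' carries its own bounding rectangle.
#'
#' @param sensors A data frame with columns `sensor_id`, `x_min_mm`,
#'   `y_min_mm`, `x_max_mm`, `y_max_mm`.
#' @param side `"left"` or `"right"`.
#' @return A tibble of class `qsf_layout` with a `side` attribute.
#' @examples
#' sensor_layout(
#'   data.frame(sensor_id = 1:2, x_min_mm = c(0, 10), y_min_mm = 0,
#'              x_max_mm = c(10, 20), y_max_mm = 10),
#'   side = "left")
#' @export
sensor_layout <- function(sensors, side = c("left", "right")) {
  side <- match.arg(side)
  req <- c("sensor_id", "x_min_mm", "y_min_mm", "x_max_mm", "y_max_mm")
  missing_cols <- setdiff(req, names(sensors))
  if (length(missing_cols)) {
    abort(paste0("layout is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "qsf_layout_error")
  }
  sensors <- tibble::as_tibble(sensors)[req]
  if (nrow(sensors) < 1L) {
    abort("layout must contain at least one sensor", class = "qsf_layout_error")
  }
  if (anyDuplicated(sensors$sensor_id)) {
    abort("sensor_id values must be unique", class = "qsf_layout_error")
  }
  bad <- sensors$x_max_mm <= sensors$x_min_mm | sensors$y_max_mm <= sensors$y_min_mm
  if (any(bad)) {
    abort(paste0("degenerate sensor rectangles (non-positive extent): sensor_id ",
                 paste(sensors$sensor_id[bad], collapse = ", ")),
          class = "qsf_layout_error")
  }
  sensors <- dplyr::arrange(sensors, .data$sensor_id)
  structure(sensors,
            side = side,
            class = c("qsf_layout", class(tibble::tibble())))
}

#' Read a sensor layout from CSV
#'
#' The layout file is a plain CSV with columns
#' `sensor_id,x_min_mm,y_min_mm,x_max_mm,y_max_mm`.
#'
#' @param path Path to the layout CSV.
#' @inheritParams sensor_layout
#' @return A [sensor_layout()] object.
#' @export
read_sensor_layout <- function(path, side = c("left", "right")) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  sensor_layout(df, side = match.arg(side))
}

#' Apply the device measurement range to pressures
#'
#' In-shoe capacitive insoles resolve pressures in a bounded range
#' (20--600 kPa for the emulated device). Values below the floor are set to
#' 0 (unresolvable, treated as no load so per-cell maxima stay
#' well-defined); values above the ceiling are clipped to the ceiling.
#' The rule is idempotent.
#'
#' @param x Numeric vector/matrix of pressures in kPa.
#' @param floor_kpa,ceiling_kpa Measurement range in kPa.
#' @return `x` with the range rule applied; attribute `n_clipped` counts
#'   samples clipped at the ceiling.
#' @export
clip_pressure_range <- function(x, floor_kpa = 20, ceiling_kpa = 600) {
  n_clipped <- sum(x > ceiling_kpa, na.rm = TRUE)
  x[x < floor_kpa] <- 0
  x[x > ceiling_kpa] <- ceiling_kpa
  attr(x, "n_clipped") <- n_clipped
  x
}

new_pressure_recording <- function(layout, frames, sample_rate, meta) {
  structure(list(layout = layout, frames = frames,
                 sample_rate = sample_rate, meta = meta),
            class = "qsf_recording")
}

#' Read an in-shoe pressure recording (PressureCSV dialect)
#'
#' PressureCSV is an open text dialect standing in for vendor ASCII exports:
#' comment headers `# layout=<file>`, `# sample_rate_hz=<hz>`,
#' `# side=left|right` (plus optional `# subject=` / `# condition=`), a
#' column header `t_s,s001,...`, then one numeric row per frame. Pressures
#' are in kPa; the device range rule ([clip_pressure_range()]) is applied on
#' read and the number of ceiling-clipped samples is reported via a message.
#'
#' @param path Path to the PressureCSV file.
#' @param layout Optional [sensor_layout()]; when `NULL` the `# layout=`
#'   header is resolved relative to `path`.
#' @param floor_kpa,ceiling_kpa Measurement range applied on read.
#' @return An object of class `qsf_recording`: a list with `layout`,
#'   `frames` (frames x sensors matrix, kPa), `sample_rate` (Hz) and `meta`.
#' @export
read_pressure_csv <- function(path, layout = NULL, floor_kpa = 20,
                              ceiling_kpa = 600) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  hdr <- lines[is_comment]
  kv <- strsplit(sub("^#\\s*", "", hdr), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  meta <- as.list(setNames(vals, trimws(keys)))

  sample_rate <- suppressWarnings(as.numeric(meta$sample_rate_hz %||% "50"))
  if (is.na(sample_rate) || sample_rate <= 0) {
    abort("malformed header: sample_rate_hz must be a positive number",
          class = "qsf_parse_error")
  }
  side <- meta$side %||% "left"
  if (!side %in% c("left", "right")) {
    abort("malformed header: side must be 'left' or 'right'",
          class = "qsf_parse_error")
  }
  if (is.null(layout)) {
    if (is.null(meta$layout)) {
      abort("malformed header: no '# layout=' line and no layout supplied",
            class = "qsf_parse_error")
    }
    layout <- read_sensor_layout(file.path(dirname(path), meta$layout),
                                 side = side)
  }

  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) {
    abort("malformed header: no column header row found", class = "qsf_parse_error")
  }
  header_line <- body_idx[1L]
  cols <- strsplit(lines[header_line], ",", fixed = TRUE)[[1L]]
  if (length(cols) < 2L || trimws(cols[1L]) != "t_s") {
    abort(sprintf("malformed header at line %d: expected 't_s,s...'", header_line),
          class = "qsf_parse_error")
  }
  n_sensors <- nrow(layout)
  if (length(cols) - 1L != n_sensors) {
    abort(sprintf("line %d: %d sensor columns but layout has %d sensors",
                  header_line, length(cols) - 1L, n_sensors),
          class = "qsf_parse_error")
  }

  data_idx <- body_idx[-1L]
  if (!length(data_idx)) {
    abort("empty recording: no frame rows", class = "qsf_parse_error")
  }
  parts <- strsplit(lines[data_idx], ",", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != n_sensors + 1L)) {
    bad <- data_idx[which(widths != n_sensors + 1L)[1L]]
    abort(sprintf("line %d: frame width %d does not match sensor count %d",
                  bad, widths[which(widths != n_sensors + 1L)[1L]] - 1L, n_sensors),
          class = "qsf_parse_error")
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(parts, use.names = FALSE)),
           nrow = length(parts), byrow = TRUE))
  if (anyNA(num)) {
    bad_row <- which(rowSums(is.na(num)) > 0)[1L]
    abort(sprintf("line %d: non-numeric value", data_idx[bad_row]),
          class = "qsf_parse_error")
  }
  t_s <- num[, 1L]
  frames <- num[, -1L, drop = FALSE]
  frames <- clip_pressure_range(frames, floor_kpa, ceiling_kpa)
  n_clipped <- attr(frames, "n_clipped")
  attr(frames, "n_clipped") <- NULL
  if (n_clipped > 0) {
    message(sprintf("read_pressure_csv: %d sample(s) clipped to %g kPa ceiling",
                    n_clipped, ceiling_kpa))
  }
  colnames(frames) <- sprintf("s%03d", layout$sensor_id)
  rec <- new_pressure_recording(
    layout, frames, sample_rate,
    meta = list(subject = meta$subject %||% NA_character_,
                side = side,
                condition = meta$condition %||% NA_character_,
                t_s = t_s,
                n_clipped = n_clipped))
  rec
}

#' Write a recording in the PressureCSV dialect
#'
#' @param rec A `qsf_recording`.
#' @param path Output file path.
#' @param layout_path Value written to the `# layout=` header line.
#' @return `path`, invisibly.
#' @export
write_pressure_csv <- function(rec, path, layout_path = "layout.csv") {
  stopifnot(inherits(rec, "qsf_recording"))
  n <- nrow(rec$frames)
  t_s <- rec$meta$t_s %||% ((seq_len(n) - 1) / rec$sample_rate)
  hdr <- c(sprintf("# layout=%s", layout_path),
           sprintf("# sample_rate_hz=%s", fmt_num(rec$sample_rate)),
           sprintf("# side=%s", attr(rec$layout, "side")))
  if (!is.na(rec$meta$subject %||% NA)) {
    hdr <- c(hdr, sprintf("# subject=%s", rec$meta$subject))
  }
  if (!is.na(rec$meta$condition %||% NA)) {
    hdr <- c(hdr, sprintf("# condition=%s", rec$meta$condition))
  }
  header_row <- paste(c("t_s", colnames(rec$frames)), collapse = ",")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(fmt_num(t_s[i]), fmt_num(rec$frames[i, ])), collapse = ",")
  }, "")
  writeLines(c(hdr, header_row, rows), path)
  invisible(path)
}

#' Write a sensor layout to CSV
#' @param layout A [sensor_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_layout <- function(layout, path) {
  readr::write_csv(as.data.frame(unclass(layout))[
    , c("sensor_id", "x_min_mm", "y_min_mm", "x_max_mm", "y_max_mm")], path)
  invisible(path)
}

#' @export
print.qsf_recording <- function(x, ...) {
  cat(sprintf("<qsf_recording> %d frames x %d sensors @ %g Hz (%s foot)\n",
              nrow(x$frames), ncol(x$frames), x$sample_rate,
              attr(x$layout, "side")))
  if (!is.na(x$meta$condition %||% NA)) {
    cat("  condition:", x$meta$condition, "\n")
  }
  invisible(x)
}

#' Read a per-foot R-ROI area table
#'
#' The area table is the unit of group-level analysis: one row per foot
#' (`subject`, `side`) and one column per walking condition holding that
#' foot's total R-ROI area in cm^2.
#'
#' @param path CSV (or XLSX, if the readxl package is installed) file with
#'   columns `subject,side,<condition>...`.
#' @param conditions Optional character vector; when given, these columns
#'   must be present and complete.
#' @return A tibble of class `qsf_area_table`.
#' @export
read_area_table <- function(path, conditions = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading XLSX area tables requires the readxl package",
            class = "qsf_parse_error")
    }
    readxl::read_excel(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  as_area_table(df, conditions = conditions)
}

#' Validate a data frame as an area table
#'
#' @param df Data frame with `subject`, `side` and condition columns.
#' @inheritParams read_area_table
#' @return A tibble of class `qsf_area_table`.
#' @export
as_area_table <- function(df, conditions = NULL) {
  if (!all(c("subject", "side") %in% names(df))) {
    abort("area table needs 'subject' and 'side' columns",
          class = "qsf_area_error")
  }
  df <- tibble::as_tibble(df)
  key <- paste(df$subject, df$side)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (subject, side) rows: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "qsf_area_error")
  }
  cond_cols <- conditions %||% setdiff(names(df), c("subject", "side"))
  missing_cols <- setdiff(cond_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing condition columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "qsf_area_error")
  }
  for (cc in cond_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      abort(sprintf("condition column '%s' is not numeric", cc),
            class = "qsf_area_error")
    }
    if (anyNA(v)) {
      abort(sprintf("missing %s area for row(s): %s", cc,
                    paste(key[is.na(v)], collapse = "; ")),
            class = "qsf_area_error")
    }
    if (any(v < 0)) {
      abort(sprintf("negative %s area for row(s): %s", cc,
                    paste(key[v < 0], collapse = "; ")),
            class = "qsf_area_error")
    }
  }
  class(df) <- c("qsf_area_table", class(tibble::tibble()))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal formatting that round-trips doubles bit-exactly
fmt_num <- function(x) {
  short <- sprintf("%g", x)
  ifelse(suppressWarnings(as.numeric(short)) == x, short, sprintf("%.17g", x))
}
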