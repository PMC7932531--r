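#' Plot a mean peak pressure map
#'
#' @param object A `qsf_mppm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qsf_mppm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$mean_kpa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mean peak\n(kPa)", option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Mean peak pressure map (n = %d stances)",
                                  object$n)) +
    ggplot2::theme_minimal()
}

#' Plot an R-ROI mask over the pressure field
#'
#' Risk cells are drawn in yellow on a dark background, matching the
#' conventional rendering of risk-region overlays.
#'
#' @param object A `qsf_rroi`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qsf_rroi <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$in_rroi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#FFD700", `FALSE` = "grey25"),
                               name = "R-ROI", labels = c(`TRUE` = "risk",
                                                          `FALSE` = "")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("R-ROI: %.2f cm^2 in %d cluster(s)",
                                  object$total_area_cm2, object$n_clusters)) +
    ggplot2::theme_minimal()
}

#' Plot a pressure-redistribution map
#'
#' The classic palette follows the usual overlay semantics: yellow for
#' significant change (decrease/increase shown as white/yellow tones in
#' published overlays), red for residual risk cells with no significant
#' change. A colourblind-safe alternative is available.
#'
#' @param object A `qsf_redistribution`.
#' @param palette `"classic"` (white = significant change, red = unchanged
#'   risk cells) or `"colorblind"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qsf_redistribution <- function(object,
                                        palette = c("classic", "colorblind"),
                                        ...) {
  palette <- match.arg(palette)
  cols <- if (palette == "classic") {
    c(unchanged = "grey25", sig_decrease = "white", sig_increase = "white",
      rroi_unchanged = "#D7191C")
  } else {
    c(unchanged = "grey40", sig_decrease = "#2C7BB6", sig_increase = "#FDAE61",
      rroi_unchanged = "#D7191C")
  }
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = cols, name = NULL, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Pressure redistribution (alpha = %g)",
                                  object$alpha)) +
    ggplot2::theme_minimal()
}

#' Summary box plot of R-ROI areas by condition
#'
#' Box plots of per-foot total R-ROI areas with the mean (circle), median
#' (square) and maximum (diamond) overlaid for each condition.
#'
#' @param table A `qsf_area_table`.
#' @param conditions Condition columns; default all non-key columns.
#' @return A ggplot.
#' @export
plot_area_summary <- function(table, conditions = NULL) {
  conditions <- conditions %||% setdiff(names(table), c("subject", "side"))
  long <- tidyr::pivot_longer(tibble::as_tibble(table),
                              cols = dplyr::all_of(conditions),
                              names_to = "condition", values_to = "area_cm2")
  long$condition <- factor(long$condition, levels = conditions)
  summ <- long |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$area_cm2),
                     median = median(.data$area_cm2),
                     max = max(.data$area_cm2), .groups = "drop") |>
    tidyr::pivot_longer(cols = c("mean", "median", "max"),
                        names_to = "stat", values_to = "area_cm2")
  ggplot2::ggplot(long, ggplot2::aes(.data$condition, .data$area_cm2)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.35, size = 1) +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(shape = .data$stat), size = 3,
                        colour = "#2C7BB6") +
    ggplot2::scale_shape_manual(values = c(mean = 16, median = 15, max = 18),
                                name = NULL) +
    ggplot2::labs(x = NULL, y = expression("total R-ROI area (" * cm^2 * ")")) +
    ggplot2::theme_minimal()
}

#' @rdname plot_area_summary
#' @param object A `qsf_area_table`.
#' @param ... Unused.
#' @export
autoplot.qsf_area_table <- function(object, ...) plot_area_summary(object)

save_png <- function(plot, path, width = 6, height = 8) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
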