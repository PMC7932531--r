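#' Run configuration
#'
#' Collects the tunable parameters of the whole pipeline under namespaced
#' keys, rejects unknown keys, and is written into every run log so an
#' analysis can be audited and re-run later (insole performance is
#' monitored over time, so provenance matters).
#'
#' @param stance A [stance_config()].
#' @param resample List with `method` and `cell_mm`.
#' @param rroi An [rroi_config()].
#' @param stats List with `alpha_family`.
#' @param min_steps Advisory minimum usable stances; default 24.
#' @param seed Optional integer seed recorded with the run.
#' @param ... Must be empty: unknown keys are an error.
#' @return A list of class `qsf_config`.
#' @export
qsf_config <- function(stance = stance_config(),
                       resample = list(method = "area_weighted", cell_mm = 5),
                       rroi = rroi_config(),
                       stats = list(alpha_family = 0.05),
                       min_steps = 24, seed = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    abort(paste0("unknown config keys: ", paste(names(extra), collapse = ", ")),
          class = "qsf_config_error")
  }
  bad <- setdiff(names(resample), c("method", "cell_mm"))
  if (length(bad)) {
    abort(paste0("unknown resample keys: ", paste(bad, collapse = ", ")),
          class = "qsf_config_error")
  }
  bad <- setdiff(names(stats), "alpha_family")
  if (length(bad)) {
    abort(paste0("unknown stats keys: ", paste(bad, collapse = ", ")),
          class = "qsf_config_error")
  }
  structure(list(stance = stance, resample = resample, rroi = rroi,
                 stats = stats, min_steps = min_steps, seed = seed),
            class = "qsf_config")
}

resolve_sequence <- function(x, cfg) {
  if (inherits(x, "qsf_grid_sequence")) return(x)
  if (inherits(x, "qsf_recording")) {
    return(resample_recording(x, method = cfg$resample$method))
  }
  if (is.character(x) && length(x) == 1L) {
    rec <- read_pressure_csv(x)
    return(resample_recording(rec, method = cfg$resample$method))
  }
  abort("expected a qsf_grid_sequence, qsf_recording, or PressureCSV path",
        class = "qsf_pipeline_error")
}

#' Analyse one foot/condition recording
#'
#' The per-recording half of the framework: stance detection, per-stance
#' peak maps, the MPPM, the statistical R-ROI mask and the foot's total
#' risk area. Warns when fewer than `cfg$min_steps` stances are available
#' (the power analysis behind the per-cell tests asks for 24).
#'
#' @param x A `qsf_grid_sequence`, `qsf_recording`, or path to a
#'   PressureCSV file.
#' @param cfg A [qsf_config()].
#' @param output_dir Optional directory; when given, MPPM and mask CSVs, a
#'   rendered map PNG and a run log are written there.
#' @return An object of class `qsf_analysis`: list with `stances`,
#'   `peaks`, `mppm`, `rroi`, `area` (one-row tibble), `config`.
#' @export
qsf_analyze <- function(x, cfg = qsf_config(), output_dir = NULL) {
  seq <- resolve_sequence(x, cfg)
  stances <- detect_stances(seq, cfg$stance)
  if (!nrow(stances)) {
    abort("no stances detected in recording", class = "qsf_pipeline_error")
  }
  if (nrow(stances) < cfg$min_steps) {
    warn(sprintf("only %d usable stances; the design requires at least %d",
                 nrow(stances), cfg$min_steps))
  }
  pk <- peak_maps(seq, stances)
  mppm <- suppressWarnings(mean_peak_map(pk, min_n = cfg$min_steps))
  rroi <- build_rroi(mppm, cfg$rroi)
  area <- tibble::tibble(
    subject = seq$meta$subject %||% NA_character_,
    side = seq$meta$side %||% NA_character_,
    condition = seq$meta$condition %||% NA_character_,
    n_steps = nrow(stances),
    total_area_cm2 = rroi$total_area_cm2)
  res <- structure(list(stances = stances, peaks = pk, mppm = mppm,
                        rroi = rroi, area = area, config = cfg),
                   class = "qsf_analysis")
  if (!is.null(output_dir)) write_analysis(res, output_dir)
  res
}

#' @export
print.qsf_analysis <- function(x, ...) {
  cat(sprintf("<qsf_analysis> %d stances; R-ROI %.2f cm^2 in %d cluster(s)\n",
              nrow(x$stances), x$rroi$total_area_cm2, x$rroi$n_clusters))
  invisible(x)
}

write_analysis <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(res$mppm), file.path(dir, "mppm.csv"))
  readr::write_csv(tidy(res$rroi), file.path(dir, "rroi_mask.csv"))
  readr::write_csv(res$stances, file.path(dir, "stances.csv"))
  readr::write_csv(res$area, file.path(dir, "area.csv"))
  save_png(autoplot(res$rroi), file.path(dir, "rroi_map.png"))
  write_run_log(res$config, file.path(dir, "run_log.txt"),
                extras = list(n_steps = nrow(res$stances),
                              total_area_cm2 = res$rroi$total_area_cm2))
  invisible(dir)
}

#' Compare two insole conditions for one foot
#'
#' Analyses both recordings, then maps where the alternative insole
#' significantly redistributes pressure relative to the reference
#' (step-paired cell-wise t-tests) and reports the residual-R-ROI pressure
#' reduction. With an empty reference risk region the comparison still
#' runs; the reduction report is then not applicable.
#'
#' @param x_ref,x_alt Reference (e.g. flat insole) and alternative
#'   recordings, as in [qsf_analyze()].
#' @param cfg A [qsf_config()].
#' @param paired Pair steps by order (default); `FALSE` for Welch.
#' @param output_dir Optional output directory.
#' @return An object of class `qsf_comparison`: list with `ref`, `alt`
#'   (`qsf_analysis`), `redistribution`, `reduction` (NULL if no reference
#'   risk region), `config`.
#' @export
qsf_compare <- function(x_ref, x_alt, cfg = qsf_config(), paired = TRUE,
                        output_dir = NULL) {
  ref <- qsf_analyze(x_ref, cfg)
  alt <- qsf_analyze(x_alt, cfg)
  n <- min(length(ref$peaks), length(alt$peaks))
  peaks_ref <- ref$peaks; peaks_alt <- alt$peaks
  if (paired && length(peaks_ref) != length(peaks_alt)) {
    # equalise by truncation to the common number of mid-walk steps
    peaks_ref <- peaks_ref[seq_len(n)]
    peaks_alt <- peaks_alt[seq_len(n)]
  }
  redist <- redistribution_map(peaks_ref, peaks_alt, ref$rroi, cfg$rroi,
                               paired = paired)
  reduction <- if (any(ref$rroi$in_rroi)) {
    residual_reduction(ref$mppm, ref$rroi, alt$mppm, alt$rroi, cfg$rroi)
  } else {
    NULL
  }
  res <- structure(list(ref = ref, alt = alt, redistribution = redist,
                        reduction = reduction, config = cfg),
                   class = "qsf_comparison")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tidy(redist), file.path(output_dir, "redistribution.csv"))
    if (!is.null(reduction)) {
      readr::write_csv(reduction, file.path(output_dir, "reduction.csv"))
    }
    save_png(autoplot(redist), file.path(output_dir, "redistribution_map.png"))
    write_run_log(cfg, file.path(output_dir, "run_log.txt"))
  }
  res
}

#' @export
print.qsf_comparison <- function(x, ...) {
  cat(sprintf("<qsf_comparison> ref %.2f cm^2 -> alt %.2f cm^2\n",
              x$ref$rroi$total_area_cm2, x$alt$rroi$total_area_cm2))
  if (is.null(x$reduction)) {
    cat("  no reference risk region; reduction not applicable\n")
  } else if (x$reduction$optimal) {
    cat(sprintf("  optimal offloading; reduction lower bound %.1f kPa\n",
                x$reduction$lower_bound_kpa))
  } else {
    cat(sprintf("  residual R-ROI reduction %.1f kPa (%.1f%%)\n",
                x$reduction$mean_reduction_kpa, x$reduction$mean_reduction_pct))
  }
  invisible(x)
}

#' Group-level analysis of an area table
#'
#' Friedman + pairwise signed-rank comparison across conditions, the
#' per-condition descriptives, and per-condition optimal-offloading counts
#' (feet whose risk region is removed entirely).
#'
#' @param table A `qsf_area_table` (or data frame accepted by
#'   [as_area_table()]).
#' @param conditions Condition columns; default all non-key columns.
#' @param cfg A [qsf_config()] (family alpha from `cfg$stats`).
#' @param output_dir Optional output directory for pairwise/descriptive
#'   CSVs and a summary box plot.
#' @return An object of class `qsf_group`: list with `comparison`,
#'   `descriptives`, `optimal` (tibble condition/n_optimal/n), `config`.
#' @export
qsf_group <- function(table, conditions = NULL, cfg = qsf_config(),
                      output_dir = NULL) {
  table <- as_area_table(table, conditions = conditions)
  conditions <- conditions %||% setdiff(names(table), c("subject", "side"))
  comparison <- compare_conditions(table, conditions,
                                   alpha_family = cfg$stats$alpha_family)
  desc <- area_descriptives(table, conditions)
  optimal <- purrr::map_dfr(conditions, function(cc) {
    tibble::tibble(condition = cc, n_optimal = count_optimal(table, cc),
                   n = nrow(table))
  })
  res <- structure(list(comparison = comparison, descriptives = desc,
                        optimal = optimal, table = table, config = cfg),
                   class = "qsf_group")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(tidy(comparison), file.path(output_dir, "pairwise.csv"))
    readr::write_csv(glance(comparison), file.path(output_dir, "friedman.csv"))
    readr::write_csv(desc, file.path(output_dir, "descriptives.csv"))
    readr::write_csv(optimal, file.path(output_dir, "optimal_counts.csv"))
    save_png(plot_area_summary(table, conditions),
             file.path(output_dir, "areas_boxplot.png"))
    write_run_log(cfg, file.path(output_dir, "run_log.txt"),
                  extras = list(n_feet = nrow(table),
                                conditions = paste(conditions, collapse = ",")))
  }
  res
}

#' @export
print.qsf_group <- function(x, ...) {
  print(x$comparison)
  cat("  optimal offloading (area = 0):\n")
  print(as.data.frame(x$optimal), row.names = FALSE)
  invisible(x)
}

write_run_log <- function(cfg, path, extras = list()) {
  ver <- as.character(utils::packageVersion("qsfoot"))
  lines <- c(sprintf("qsfoot %s run log (%s)", ver,
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             deparse_config(cfg),
             if (length(extras)) {
               paste0(names(extras), " = ",
                      vapply(extras, function(x) paste(format(x), collapse = ","), ""))
             })
  writeLines(lines, path)
  invisible(path)
}

deparse_config <- function(cfg) {
  flat <- function(x, prefix) {
    if (is.list(x)) {
      unlist(purrr::imap(unclass(x), function(v, k) {
        flat(v, if (nzchar(prefix)) paste0(prefix, ".", k) else k)
      }), use.names = FALSE)
    } else {
      paste0(prefix, " = ",
             if (is.null(x)) "NULL" else paste(format(x), collapse = ","))
    }
  }
  flat(unclass(cfg), "")
}
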