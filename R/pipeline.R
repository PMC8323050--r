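#' Run the full analysis on a cohort
#'
#' Chains the pipeline stages: missing-data exclusion, cosinor fitting
#' (fixed-24 and bounded free period), ledger feature extraction, linear
#' group comparisons, and circular acrophase comparisons.
#'
#' @param samples Samples tibble ([read_profiles()] dialect).
#' @param exclusion_threshold Maximum tolerated missing slots per series.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param pairings Group pairings to compare.
#' @param p_adjust `"none"` or `"BH"`.
#' @return A list with tibbles `exclusions`, `fits`, `features`,
#'   `comparisons`, `circular`, `summaries`, and a `manifest` list of stage
#'   counts and warnings.
#' @export
run_analysis <- function(samples, exclusion_threshold = 4,
                         t_variant = c("pooled", "welch"),
                         pairings = list(c("control", "depression"),
                                         c("control", "recovery")),
                         p_adjust = c("none", "BH")) {
  t_variant <- match.arg(t_variant)
  p_adjust <- match.arg(p_adjust)
  warnings <- character(0)

  n_series <- nrow(dplyr::distinct(samples, .data$subject_id, .data$analyte))
  excl <- apply_exclusion(samples, threshold = exclusion_threshold)
  n_retained <- nrow(dplyr::distinct(excl$retained, .data$subject_id, .data$analyte))
  if (n_retained == 0) {
    stop("no profiles retained: ", nrow(excl$excluded), " of ", n_series,
         " series excluded at threshold ", exclusion_threshold)
  }

  # drop pairings whose groups are absent from the retained data
  present <- unique(excl$retained$group)
  usable <- Filter(function(p) all(p %in% present), pairings)
  if (length(usable) < length(pairings)) {
    warnings <- c(warnings, "some pairings skipped: group absent from retained data")
  }
  if (length(usable) == 0) stop("no requested pairing has both groups present")

  fits <- cosinor_fit_table(excl$retained)
  if (any(!fits$fit_ok)) {
    warnings <- c(warnings, sprintf("%d series had too few points to fit", sum(!fits$fit_ok)))
  }
  if (any(fits$degenerate, na.rm = TRUE)) {
    warnings <- c(warnings, sprintf("%d degenerate (flat) fits", sum(fits$degenerate, na.rm = TRUE)))
  }
  features <- feature_table(excl$retained, fits)
  comparisons <- compare_all(features, pairings = usable,
                             variant = t_variant, p_adjust = p_adjust)
  circular <- circular_comparison_table(fits, pairings = usable)
  if (any(circular$assumption_warning, na.rm = TRUE)) {
    warnings <- c(warnings, "Watson-Williams low-concentration assumption flag raised")
  }
  summaries <- group_feature_summary(features)

  manifest <- list(
    n_series_in = n_series,
    n_series_retained = n_retained,
    n_series_excluded = nrow(excl$excluded),
    n_fits = nrow(fits),
    n_features = nrow(features),
    n_comparisons = nrow(comparisons),
    warnings = warnings
  )
  list(exclusions = excl$excluded, fits = fits, features = features,
       comparisons = comparisons, circular = circular, summaries = summaries,
       manifest = manifest)
}

write_manifest <- function(manifest, dir, extra = list()) {
  m <- c(extra, manifest)
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}

#' Command-style entry points
#'
#' Thin wrappers chaining the pipeline stages to files, suitable for
#' scripting: `cmd_simulate()` writes a simulated cohort, `cmd_analyze()`
#' runs the analysis on a profiles CSV and writes one CSV per stage plus a
#' run manifest, `cmd_report()` renders profile and circular-phase figures
#' from an analysis directory (requires ggplot2).
#'
#' @param config Path to a YAML cohort configuration ([read_cohort_config()]
#'   format), or a `cohort_config` object, or NULL for the study default.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configuration seed.
#' @return Each command returns (invisibly) a list of the files it wrote.
#' @export
cmd_simulate <- function(config = NULL, out_dir = "simulated", seed = NULL) {
  cfg <- if (is.null(config)) {
    default_cohort_config()
  } else if (inherits(config, "cohort_config")) {
    config
  } else {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    read_cohort_config(config)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_cohort(cfg, dir = out_dir)
  manifest <- list(
    stage = "simulate", seed = cfg$seed,
    package_version = as.character(utils::packageVersion("circasal")),
    n_subjects = length(unique(sim$samples$subject_id)),
    n_series = nrow(dplyr::distinct(sim$samples, .data$subject_id, .data$analyte)),
    n_rows = nrow(sim$samples),
    outputs = unname(unlist(sim$paths))
  )
  write_manifest(manifest, out_dir)
  invisible(c(sim$paths, list(manifest = file.path(out_dir, "manifest.yaml"))))
}

#' @rdname cmd_simulate
#' @param profiles_path Path to a profiles CSV.
#' @inheritParams run_analysis
#' @export
cmd_analyze <- function(profiles_path, out_dir = "analysis",
                        exclusion_threshold = 4,
                        t_variant = c("pooled", "welch"),
                        p_adjust = c("none", "BH")) {
  t_variant <- match.arg(t_variant)
  p_adjust <- match.arg(p_adjust)
  samples <- read_profiles(profiles_path)
  res <- run_analysis(samples, exclusion_threshold = exclusion_threshold,
                      t_variant = t_variant, p_adjust = p_adjust)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    fits = file.path(out_dir, "fits.csv"),
    features = file.path(out_dir, "features.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    circular = file.path(out_dir, "circular.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    summaries = file.path(out_dir, "summaries.csv")
  )
  readr::write_csv(res$fits, paths$fits, na = "")
  readr::write_csv(res$features, paths$features, na = "")
  readr::write_csv(res$comparisons, paths$comparisons, na = "")
  readr::write_csv(res$circular, paths$circular, na = "")
  readr::write_csv(res$exclusions, paths$exclusions, na = "")
  readr::write_csv(res$summaries, paths$summaries, na = "")
  manifest <- c(list(stage = "analyze", input = profiles_path,
                     package_version = as.character(utils::packageVersion("circasal")),
                     exclusion_threshold = exclusion_threshold,
                     t_variant = t_variant),
                res$manifest, list(outputs = unname(unlist(paths))))
  write_manifest(manifest, out_dir)
  invisible(c(paths, list(manifest = file.path(out_dir, "manifest.yaml"))))
}

#' @rdname cmd_simulate
#' @param analysis_dir Directory written by `cmd_analyze()`.
#' @param profiles_path Path to the profiles CSV the analysis used.
#' @export
cmd_report <- function(analysis_dir, profiles_path, out_dir = analysis_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("cmd_report requires the ggplot2 package")
  }
  fits_path <- file.path(analysis_dir, "fits.csv")
  if (!file.exists(fits_path)) {
    stop("no analysis outputs in '", analysis_dir, "' (missing fits.csv); run cmd_analyze first")
  }
  samples <- read_profiles(profiles_path)
  fits <- readr::read_csv(fits_path, show_col_types = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  for (a in unique(samples$analyte)) {
    for (g in unique(samples$group)) {
      p <- plot_group_profile(samples, fits, analyte = a, group = g)
      f <- file.path(out_dir, sprintf("profile_%s_%s.png", a, g))
      ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 150)
      files <- c(files, f)
    }
    p <- plot_phase_circle(fits, analyte = a)
    f <- file.path(out_dir, sprintf("phases_%s.png", a))
    ggplot2::ggsave(f, p, width = 5, height = 5, dpi = 150)
    files <- c(files, f)
  }
  summary_path <- file.path(out_dir, "report.txt")
  writeLines(report_text(analysis_dir), summary_path)
  invisible(c(files, summary_path))
}

report_text <- function(analysis_dir) {
  comp <- readr::read_csv(file.path(analysis_dir, "comparisons.csv"),
                          show_col_types = FALSE)
  circ <- readr::read_csv(file.path(analysis_dir, "circular.csv"),
                          show_col_types = FALSE)
  sig <- comp[!is.na(comp$significant) & comp$significant, ]
  c(sprintf("comparisons: %d (%d computable, %d significant at p < .05)",
            nrow(comp), sum(comp$computable), nrow(sig)),
    if (nrow(sig)) sprintf("  %s %s %s vs %s: t = %.3f, p = %.4f",
                           sig$analyte, sig$feature, sig$group_a, sig$group_b,
                           sig$t_statistic, sig$p_value),
    sprintf("circular (Watson-Williams): %d comparisons", nrow(circ)),
    sprintf("  %s %s vs %s: F = %s, p = %s",
            circ$analyte, circ$group_a, circ$group_b,
            ifelse(is.na(circ$F_statistic), "-", sprintf("%.3f", circ$F_statistic)),
            ifelse(is.na(circ$p_value), "-", sprintf("%.4f", circ$p_value))))
}

#' Diagnostic figures
#'
#' `plot_group_profile()` draws the pointwise group-mean profile (mean +-
#' SEM) over the two-day elapsed axis with the cosinor curve fitted to the
#' group-mean profile. `plot_phase_circle()` draws each subject's acrophase
#' on a 24-h dial (00:00 at the top, clockwise, 12:00 at the bottom) with
#' the group mean vectors.
#'
#' @param samples Samples tibble.
#' @param fits Fit table (used for per-subject acrophases).
#' @param analyte,group Panel selectors.
#' @return A ggplot object.
#' @export
plot_group_profile <- function(samples, fits, analyte, group) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  sub <- samples[samples$analyte == analyte & samples$group == group, ]
  if (nrow(sub) == 0) stop("no samples for ", analyte, " / ", group)
  avg <- sub |>
    dplyr::group_by(.data$elapsed_time) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sem = sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$value))),
                     .groups = "drop")
  fit <- fit_cosinor(avg$elapsed_time, avg$mean, period = 24)
  grid <- tibble::tibble(elapsed_time = seq(0, max(sub$elapsed_time), by = 0.25))
  grid$fitted <- predict_cosinor(fit, grid$elapsed_time, timescale = "elapsed")
  unit <- if (analyte == "cortisol") "ng/ml" else "pg/ml"
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$elapsed_time, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.6, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$elapsed_time, y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::scale_x_continuous(breaks = seq(0, 45, by = 6)) +
    ggplot2::labs(x = "elapsed time (h, from day-1 08:00)",
                  y = sprintf("%s (%s, mean ± SEM)", analyte, unit),
                  title = sprintf("%s, %s group (two consecutive days)", analyte, group)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_group_profile
#' @export
plot_phase_circle <- function(fits, analyte) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  fa <- fits[fits$analyte == analyte & !is.na(fits$acrophase_clock), ]
  if (nrow(fa) == 0) stop("no usable acrophases for ", analyte)
  fa$len <- ifelse(is.na(fa$r_squared), 1, pmax(fa$r_squared, 0))
  mv <- fa |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      clock = mean_vector(phase_angle(.data$acrophase_clock))$mean_clock,
      len = mean_vector(phase_angle(.data$acrophase_clock))$resultant_length,
      .groups = "drop")
  ggplot2::ggplot(fa) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$acrophase_clock, xend = .data$acrophase_clock,
                   y = 0, yend = .data$len, colour = .data$group),
      alpha = 0.5,
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::geom_segment(
      data = mv,
      ggplot2::aes(x = .data$clock, xend = .data$clock, y = 0, yend = .data$len,
                   colour = .data$group),
      linewidth = 1.2,
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"))) +
    # 00:00 at the top, clockwise, 12:00 at the bottom
    ggplot2::coord_polar(start = 0, direction = 1) +
    ggplot2::scale_x_continuous(limits = c(0, 24), breaks = seq(0, 21, by = 3)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s acrophases (24-h dial)", analyte)) +
    ggplot2::theme_minimal()
}
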