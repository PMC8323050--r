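#' The twelve-parameter rhythm ledger
#'
#' For each subject x analyte series the pipeline summarizes the two-day
#' profile with twelve parameters, in a fixed panel order:
#'
#' 1. `period` — period of the rhythm from the bounded free-period cosinor
#'    fit, hours.
#' 2. `acrophase_clock` — clock time of the fitted maximum from the
#'    fixed-24 h cosinor fit, hours.
#' 3. `fitted_peak` — mesor + amplitude of the fixed-24 h fit.
#' 4. `fitted_mesor` — mesor of the fixed-24 h fit.
#' 5. `avg_24h` — plain mean of all present measurements over both days.
#' 6. `max_level` — the measurement at the analyte's anchor slot: day-2
#'    08:00 for cortisol (its morning maximum) and day-2 05:00 for
#'    melatonin (its nocturnal maximum); missing if that slot is missing.
#' 7. `range` — empirical maximum minus empirical minimum over all present
#'    measurements, both days.
#' 8. `two_day_diff` — mean absolute difference between matched clock-time
#'    measurements on the two days (a replicability statistic).
#' 9. `slope_day1` — ordinary least-squares slope of value against elapsed
#'    hour over the day-1 daytime triplet 08:00, 11:00, 14:00.
#' 10. `slope_day2` — same over the day-2 daytime triplet.
#' 11. `slope_night1` — night slope over the analyte's night triplet.
#'     Cortisol climbs into the morning peak, so its triplet is 01:00,
#'     05:00 and the following 08:00 (elapsed 17, 21, 24 for night 1);
#'     melatonin peaks during the night, so its triplet is 22:00, 01:00,
#'     05:00 (elapsed 14, 17, 21).
#' 12. `slope_night2` — the night triplet shifted +24 h. For cortisol this
#'     would end at a third-morning 08:00 that is never sampled, so under
#'     the canonical two-day schedule it is a two-point slope and is
#'     flagged as degraded.
#'
#' Slopes are always computed against elapsed time, never against raw clock
#' numerals, so the post-midnight samples keep their true temporal order. A
#' slope with fewer than 2 present points is missing; with exactly 2 it is
#' the two-point slope, flagged in `flags`.
#'
#' @param sub A samples tibble for one subject x analyte (all scheduled
#'   slots present as rows, NA = missing).
#' @param fit_fixed The fixed-24 h `cosinor_fit` for this series (or NULL).
#' @param fit_free The free-period `cosinor_fit` (or NULL; period feature
#'   is then missing).
#' @param two_day_stat `"mean"` (default) for the mean absolute matched
#'   difference, `"sum"` for the accumulated absolute difference.
#' @return A one-row tibble: keys, the 12 features in panel order, and a
#'   `flags` string (semicolon-separated quality flags, "" if clean).
#' @export
extract_features <- function(sub, fit_fixed = NULL, fit_free = NULL,
                             two_day_stat = c("mean", "sum")) {
  two_day_stat <- match.arg(two_day_stat)
  stopifnot(length(unique(sub$subject_id)) == 1,
            length(unique(sub$analyte)) == 1)
  tibble::as_tibble(extract_features_core(sub, fit_fixed, fit_free, two_day_stat))
}

extract_features_core <- function(sub, fit_fixed, fit_free, two_day_stat) {
  analyte <- sub$analyte[1]
  flags <- character(0)

  vals <- sub$value[!is.na(sub$value)]
  avg_24h <- if (length(vals) > 0) mean(vals) else NA_real_
  rng <- if (length(vals) > 0) max(vals) - min(vals) else NA_real_

  anchor_clock <- if (analyte == "cortisol") 8 else 5
  anchor <- sub$value[sub$day == 2 & sub$clock_time == anchor_clock]
  max_level <- if (length(anchor) == 1) anchor else NA_real_
  if (is.na(max_level)) flags <- c(flags, "anchor_missing")

  d1 <- sub[sub$day == 1, ]
  d2 <- sub[sub$day == 2, ]
  diffs <- abs(d1$value - d2$value[match(d1$clock_time, d2$clock_time)])
  diffs <- diffs[!is.na(diffs)]
  two_day_diff <- if (length(diffs) == 0) NA_real_ else {
    if (two_day_stat == "mean") mean(diffs) else sum(diffs)
  }

  slope_of <- function(elapsed_pts, label) {
    keep <- sub$elapsed_time %in% elapsed_pts & !is.na(sub$value)
    x <- sub$elapsed_time[keep]
    y <- sub$value[keep]
    if (length(x) < 2) {
      flags <<- c(flags, paste0(label, "_missing"))
      return(NA_real_)
    }
    if (length(x) == 2) flags <<- c(flags, paste0(label, "_2pt"))
    # ordinary least-squares slope against elapsed time
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }

  day_triplet <- c(0, 3, 6)
  night_triplet <- if (analyte == "cortisol") c(17, 21, 24) else c(14, 17, 21)
  slope_day1 <- slope_of(day_triplet, "slope_day1")
  slope_day2 <- slope_of(day_triplet + 24, "slope_day2")
  slope_night1 <- slope_of(night_triplet, "slope_night1")
  slope_night2 <- slope_of(night_triplet + 24, "slope_night2")

  get_fit <- function(fit, what) {
    if (is.null(fit) || is.na(fit[[what]])) NA_real_ else fit[[what]]
  }
  period <- get_fit(fit_free, "period")
  acrophase_clock <- get_fit(fit_fixed, "acrophase_clock")
  fitted_mesor <- get_fit(fit_fixed, "mesor")
  amplitude <- get_fit(fit_fixed, "amplitude")
  fitted_peak <- if (is.na(fitted_mesor) || is.na(amplitude)) NA_real_ else fitted_mesor + amplitude
  if (!is.null(fit_fixed) && isTRUE(fit_fixed$degenerate)) flags <- c(flags, "degenerate_fit")

  list(
    subject_id = sub$subject_id[1],
    group = sub$group[1],
    analyte = analyte,
    period = period,
    acrophase_clock = acrophase_clock,
    fitted_peak = fitted_peak,
    fitted_mesor = fitted_mesor,
    avg_24h = avg_24h,
    max_level = max_level,
    range = rng,
    two_day_diff = two_day_diff,
    slope_day1 = slope_day1,
    slope_day2 = slope_day2,
    slope_night1 = slope_night1,
    slope_night2 = slope_night2,
    flags = paste(flags, collapse = ";")
  )
}

#' Names of the ledger features, in panel order
#' @return Character vector of the 12 feature column names.
#' @export
feature_names <- function() {
  c("period", "acrophase_clock", "fitted_peak", "fitted_mesor",
    "avg_24h", "max_level", "range", "two_day_diff",
    "slope_day1", "slope_day2", "slope_night1", "slope_night2")
}

#' Build the feature table for a cohort
#'
#' One ledger row per subject x analyte, combining the raw-profile features
#' with the cosinor-derived ones from a fit table.
#'
#' @param samples Samples tibble ([read_profiles()] dialect).
#' @param fits Fit table from [cosinor_fit_table()]. Every fit row must have
#'   a matching profile.
#' @inheritParams extract_features
#' @return A tibble with keys, the 12 features and `flags`.
#' @export
feature_table <- function(samples, fits = cosinor_fit_table(samples),
                          two_day_stat = c("mean", "sum")) {
  two_day_stat <- match.arg(two_day_stat)
  prof_keys <- dplyr::distinct(samples, .data$subject_id, .data$analyte)
  fit_keys <- dplyr::distinct(fits, .data$subject_id, .data$analyte)
  orphan <- dplyr::anti_join(fit_keys, prof_keys, by = c("subject_id", "analyte"))
  if (nrow(orphan) > 0) {
    stop("fit table contains subject x analyte pairs absent from the profiles: ",
         paste(paste(orphan$subject_id, orphan$analyte), collapse = ", "))
  }
  skey <- paste(samples$subject_id, samples$analyte, sep = "\r")
  fkey <- paste(fits$subject_id, fits$analyte, sep = "\r")
  rows <- vector("list", nrow(prof_keys))
  for (i in seq_len(nrow(prof_keys))) {
    key <- paste(prof_keys$subject_id[i], prof_keys$analyte[i], sep = "\r")
    sub <- samples[skey == key, ]
    f <- fits[fkey == key, ]
    fit_fixed <- NULL
    fit_free <- NULL
    if (nrow(f) == 1 && isTRUE(f$fit_ok)) {
      fit_fixed <- list(mesor = f$mesor, amplitude = f$amplitude,
                        acrophase_clock = f$acrophase_clock,
                        degenerate = isTRUE(f$degenerate))
      if (!is.na(f$period_free)) fit_free <- list(period = f$period_free)
    }
    rows[[i]] <- extract_features_core(sub, fit_fixed, fit_free, two_day_stat)
  }
  cols <- lapply(stats::setNames(nm = names(rows[[1]])), function(nm) {
    unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  })
  tibble::as_tibble(cols)
}

#' Write a feature table to CSV
#'
#' @param features Feature table from [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly. Missing features become empty cells.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path, na = "")
  invisible(path)
}
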