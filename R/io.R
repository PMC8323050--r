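#' Read timed hormone profiles from CSV
#'
#' Reads a long-format table of timed saliva hormone measurements and
#' validates it against the sampling schedule. The expected columns are
#' `subject_id`, `group`, `analyte`, `day`, `clock_time`, `value`; an empty
#' `value` cell denotes a missing measurement. Scheduled slots absent from
#' the file are completed as missing so that every subject x analyte series
#' carries the full two-day grid (14 slots canonically), which keeps the
#' anchored-maximum features and the missing-data exclusion rule well
#' defined.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schedule Within-day clock times, in collection order.
#' @param strict If `TRUE` (default), rows whose `clock_time` is not on the
#'   schedule are rejected; if `FALSE` they are dropped with a warning.
#' @return A tibble of samples with columns `subject_id`, `group`, `analyte`,
#'   `day`, `clock_time`, `elapsed_time`, `value` (NA = missing), sorted by
#'   subject, analyte and elapsed time, one row per scheduled slot. The
#'   schedule is attached as attribute `"schedule"`.
#' @seealso [write_profiles()], [profile_summary()]
#' @export
read_profiles <- function(path, schedule = canonical_schedule(), strict = TRUE) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      analyte = readr::col_character(),
      day = readr::col_integer(),
      clock_time = readr::col_double(),
      value = readr::col_double()
    ), progress = FALSE),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  need <- c("subject_id", "group", "analyte", "day", "clock_time", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("'", path, "' lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed CSV at line(s) ", paste(head(prob$row, 5), collapse = ", "),
         ": ", prob$expected[1], " expected")
  }
  validate_samples(raw[need], schedule = schedule, strict = strict)
}

# Validate a raw samples data frame and complete the schedule grid.
# Errors carry 1-based data row numbers (header excluded).
validate_samples <- function(raw, schedule = canonical_schedule(), strict = TRUE) {
  raw <- tibble::as_tibble(raw)
  rowno <- seq_len(nrow(raw))
  fail <- function(rows, what) {
    stop("validation failed, row(s) ", paste(head(rows, 10), collapse = ", "),
         ": ", what, call. = FALSE)
  }

  bad <- rowno[!(raw$group %in% .groups)]
  if (length(bad)) fail(bad, paste0("unknown group label (expected one of ",
                                    paste(.groups, collapse = ", "), ")"))
  bad <- rowno[!(raw$analyte %in% .analytes)]
  if (length(bad)) fail(bad, paste0("unknown analyte (expected one of ",
                                    paste(.analytes, collapse = ", "), ")"))
  bad <- rowno[is.na(raw$day) | !(raw$day %in% c(1L, 2L))]
  if (length(bad)) fail(bad, "day must be 1 or 2")
  bad <- rowno[!is.na(raw$value) & raw$value < 0]
  if (length(bad)) fail(bad, "negative concentration")

  off <- !(raw$clock_time %in% schedule)
  if (any(off)) {
    if (strict) fail(rowno[off], "clock_time not on the sampling schedule")
    warning(sum(off), " off-schedule row(s) dropped")
    raw <- raw[!off, , drop = FALSE]
  }

  key <- paste(raw$subject_id, raw$analyte, raw$day, raw$clock_time, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) fail(which(dup), "duplicate (subject, analyte, day, clock_time)")

  subj_group <- stats::aggregate(group ~ subject_id, data = raw,
                                 FUN = function(g) length(unique(g)))
  if (any(subj_group$group > 1)) {
    fail(rowno[raw$subject_id %in% subj_group$subject_id[subj_group$group > 1]],
         "subject assigned to more than one group")
  }

  raw$elapsed_time <- elapsed_time(raw$day, raw$clock_time, schedule)

  grid <- schedule_grid(schedule)
  keys <- dplyr::distinct(raw, .data$subject_id, .data$group, .data$analyte)
  full <- tidyr::crossing(keys, grid)
  out <- dplyr::left_join(full, raw,
                          by = c("subject_id", "group", "analyte",
                                 "day", "clock_time", "elapsed_time"))
  out <- dplyr::arrange(out, .data$subject_id, .data$analyte, .data$elapsed_time)
  out <- out[, c("subject_id", "group", "analyte", "day", "clock_time",
                 "elapsed_time", "value")]
  attr(out, "schedule") <- schedule
  out
}

#' Write timed hormone profiles to CSV
#'
#' Writes profiles in the same long-format dialect that [read_profiles()]
#' accepts. Missing measurements are written as empty cells, never as zeros,
#' so the round trip `read_profiles(write_profiles(p))` reproduces `p`.
#'
#' @param samples A samples tibble as returned by [read_profiles()] or
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(samples, path) {
  cols <- c("subject_id", "group", "analyte", "day", "clock_time", "value")
  stopifnot(all(cols %in% names(samples)))
  readr::write_csv(samples[, cols], path, na = "")
  invisible(path)
}

#' Per-profile summary of scheduled and missing slots
#'
#' One row per subject x analyte series with the number of scheduled slots,
#' the number of present measurements and `n_missing`, the count the
#' missing-data exclusion rule consumes.
#'
#' @inheritParams write_profiles
#' @return A tibble with columns `subject_id`, `group`, `analyte`,
#'   `n_slots`, `n_present`, `n_missing`.
#' @export
profile_summary <- function(samples) {
  samples |>
    dplyr::group_by(.data$subject_id, .data$group, .data$analyte) |>
    dplyr::summarise(
      n_slots = dplyr::n(),
      n_present = sum(!is.na(.data$value)),
      n_missing = sum(is.na(.data$value)),
      .groups = "drop"
    )
}

#' Read an analysis configuration file
#'
#' A small YAML configuration with keys `schedule` (within-day clock times),
#' `units` (named list, analyte to unit string) and `exclusion_threshold`
#' (maximum tolerated missing slots; more than this excludes the series).
#' Absent keys fall back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `schedule`, `units`, `exclusion_threshold`.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(
    schedule = if (!is.null(cfg$schedule)) as.numeric(cfg$schedule) else canonical_schedule(),
    units = if (!is.null(cfg$units)) cfg$units else list(cortisol = "ng/ml", melatonin = "pg/ml"),
    exclusion_threshold = if (!is.null(cfg$exclusion_threshold)) as.integer(cfg$exclusion_threshold) else 4L
  )
}
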