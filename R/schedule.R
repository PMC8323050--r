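#' Sampling schedules and the elapsed-time convention
#'
#' Saliva is collected at fixed clock times over two consecutive sampling
#' days. The canonical schedule has seven collections per day at 08:00,
#' 11:00, 14:00, 19:00, 22:00, 01:00 and 05:00. The two night collections
#' (01:00, 05:00) belong to the sampling day that *precedes* them on the
#' calendar: the day-1 night samples are drawn in the small hours of calendar
#' day 2. All analysis therefore runs on a continuous elapsed-time axis with
#' origin at the first scheduled sample (day-1 08:00 = 0 h), on which the
#' canonical slots fall at 0, 3, 6, 11, 14, 17, 21 h (day 1) and those
#' values + 24 (day 2).
#'
#' `schedule_offsets()` converts the within-day clock times (listed in
#' collection order) into hour offsets from the first slot, accumulating
#' forward across midnight.
#'
#' @param clock_times Numeric vector of within-day collection clock times in
#'   hours, in collection order starting from the first sample of the day.
#' @return `canonical_schedule()` returns the canonical clock-time vector;
#'   `schedule_offsets()` the corresponding offsets from the day's first slot.
#' @examples
#' canonical_schedule()
#' schedule_offsets(canonical_schedule())
#' @export
canonical_schedule <- function() c(8, 11, 14, 19, 22, 1, 5)

#' @rdname canonical_schedule
#' @export
schedule_offsets <- function(clock_times = canonical_schedule()) {
  stopifnot(is.numeric(clock_times), length(clock_times) >= 1,
            all(clock_times >= 0 & clock_times < 24))
  gaps <- diff(clock_times) %% 24
  if (any(gaps == 0)) stop("schedule contains a repeated clock time")
  c(0, cumsum(gaps))
}

#' Convert (day, clock time) to elapsed hours and back
#'
#' `elapsed_time()` maps a sampling day and clock time onto the continuous
#' elapsed axis (hours since day-1 first slot). `elapsed_to_slot()` inverts
#' the map for on-schedule elapsed times.
#'
#' @param day Integer sampling day (1 or 2).
#' @param clock_time Clock time in hours; must belong to `schedule`.
#' @param schedule Within-day schedule clock times (collection order).
#' @param elapsed Elapsed hours since the first scheduled sample.
#' @return `elapsed_time()`: numeric hours. `elapsed_to_slot()`: a tibble
#'   with columns `day` and `clock_time`.
#' @examples
#' elapsed_time(1, 1)   # day-1 01:00 sample, drawn on calendar day 2 -> 17
#' elapsed_time(2, 8)   # 24
#' elapsed_to_slot(c(0, 17, 45))
#' @export
elapsed_time <- function(day, clock_time, schedule = canonical_schedule()) {
  stopifnot(length(day) == length(clock_time))
  offs <- schedule_offsets(schedule)
  idx <- match(clock_time, schedule)
  if (anyNA(idx)) {
    bad <- unique(clock_time[is.na(idx)])
    stop("clock time(s) not on the schedule: ", paste(bad, collapse = ", "))
  }
  if (!all(day %in% c(1L, 2L))) stop("day must be 1 or 2")
  offs[idx] + (day - 1) * 24
}

#' @rdname elapsed_time
#' @export
elapsed_to_slot <- function(elapsed, schedule = canonical_schedule()) {
  offs <- schedule_offsets(schedule)
  day <- ifelse(elapsed >= 24, 2L, 1L)
  off <- elapsed - (day - 1) * 24
  idx <- match(off, offs)
  if (anyNA(idx)) stop("elapsed time(s) not on the schedule: ",
                       paste(unique(elapsed[is.na(idx)]), collapse = ", "))
  tibble::tibble(day = day, clock_time = schedule[idx])
}

#' Clock time of an elapsed hour
#'
#' The clock time corresponding to an elapsed hour, given that the axis
#' origin sits at the first scheduled clock time (08:00 canonically).
#'
#' @inheritParams elapsed_time
#' @return Clock hours in `[0, 24)`.
#' @export
clock_of_elapsed <- function(elapsed, schedule = canonical_schedule()) {
  (schedule[1] + elapsed) %% 24
}

# Full two-day slot grid for one subject x analyte: day, clock_time, elapsed.
schedule_grid <- function(schedule = canonical_schedule(), n_days = 2) {
  offs <- schedule_offsets(schedule)
  tibble::tibble(
    day = rep(seq_len(n_days), each = length(schedule)),
    clock_time = rep(schedule, n_days),
    elapsed_time = rep(offs, n_days) + (rep(seq_len(n_days), each = length(schedule)) - 1) * 24
  )
}
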