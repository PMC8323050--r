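#' Specify a simulated group
#'
#' A group specification holds, per analyte, the between-subject truth
#' distributions from which each simulated subject's cosinor parameters are
#' drawn: mesor and amplitude as truncated normals (truncated at 0),
#' acrophase as a wrapped normal on the 24-h clock, and the free period as
#' a normal centred at 24 h. The noise coefficient of variation and the
#' per-slot missingness probability complete the observation model.
#'
#' @param label Group label (see [group_labels()]).
#' @param n_subjects Number of subjects.
#' @param analytes Named list, one entry per analyte, each a list with
#'   fields `mesor` (c(mean, sd)), `amplitude` (c(mean, sd)),
#'   `acrophase` (c(circular mean clock hour, circular sd in hours)),
#'   `period` (c(mean, sd)), `noise_cv` (fraction) and `missing_rate`
#'   (probability in `[0, 1)`).
#' @return A list of class `group_spec`.
#' @seealso [default_cohort_config()] for study-default specifications.
#' @export
group_spec <- function(label, n_subjects, analytes) {
  stopifnot(label %in% .groups, n_subjects >= 1, is.list(analytes),
            all(names(analytes) %in% .analytes))
  for (a in analytes) {
    stopifnot(length(a$mesor) == 2, a$mesor[2] >= 0,
              length(a$amplitude) == 2, a$amplitude[2] >= 0,
              length(a$acrophase) == 2, a$acrophase[2] >= 0,
              length(a$period) == 2, a$period[2] >= 0,
              a$noise_cv >= 0, a$missing_rate >= 0, a$missing_rate < 1)
  }
  structure(list(label = label, n_subjects = as.integer(n_subjects),
                 analytes = analytes),
            class = "group_spec")
}

# Truth distribution for one analyte: hormone-scale defaults.
# Cortisol (ng/ml) peaks at the 08:00 waking sample; melatonin (pg/ml)
# peaks in the late night, around 03:50 clock time in controls. The noise
# CVs default to the intra-assay imprecision of the respective ELISA
# (6.1% cortisol, 10.8% melatonin).
analyte_truth <- function(analyte,
                          mesor, amplitude, acrophase,
                          period = c(24, 0),
                          noise_cv = if (analyte == "cortisol") 0.061 else 0.108,
                          missing_rate = 0.05) {
  list(mesor = mesor, amplitude = amplitude, acrophase = acrophase,
       period = period, noise_cv = noise_cv, missing_rate = missing_rate)
}

control_truths <- function() {
  list(
    cortisol = analyte_truth("cortisol",
                             mesor = c(4, 0.8), amplitude = c(3.5, 0.7),
                             acrophase = c(8, 1)),
    melatonin = analyte_truth("melatonin",
                              mesor = c(12, 2.5), amplitude = c(10, 2.5),
                              acrophase = c(3.83, 1))
  )
}

depression_truths <- function() {
  tr <- control_truths()
  # damped cortisol rhythm (lower morning maximum), melatonin phase advance
  # to about 01:30 clock time
  tr$cortisol$amplitude <- c(2.2, 0.7)
  tr$melatonin$acrophase <- c(1.5, 1)
  tr
}

#' Study-default simulation configuration
#'
#' Builds the default cohort configuration the package's simulations use:
#' group sizes matching the analyzed study sets (cortisol 12 control / 10
#' depression / 4 recovery; melatonin 12 / 8 / 3), control cortisol peaking
#' at the 08:00 clock time and control melatonin around 03:50; the
#' depression group carries a damped cortisol amplitude and a melatonin
#' acrophase around 01:30 (about a 2.3-h phase advance); the recovery group
#' duplicates the control distributions. Assay noise defaults to the
#' intra-assay CVs (6.1% cortisol, 10.8% melatonin) and missingness to a
#' sporadic 5% per slot.
#'
#' @param analyte `"cortisol"`, `"melatonin"` or `"both"`. Because the
#'   study's analyzed group sizes differ by analyte, `"both"` simulates the
#'   two analytes as separate cohorts with per-analyte sizes.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @param missing_rate Per-slot missingness probability applied to every
#'   group.
#' @return A list of class `cohort_config` with elements `groups` (list of
#'   [group_spec()]), `schedule`, `n_days`, `seed`.
#' @export
default_cohort_config <- function(analyte = c("both", "cortisol", "melatonin"),
                                  seed = 1L, missing_rate = 0.05) {
  analyte <- match.arg(analyte)
  sizes <- list(cortisol = c(control = 12, depression = 10, recovery = 4),
                melatonin = c(control = 12, depression = 8, recovery = 3))
  truths <- list(control = control_truths(), depression = depression_truths(),
                 recovery = control_truths())
  wanted <- if (analyte == "both") .analytes[1:2] else analyte
  groups <- list()
  for (g in c("control", "depression", "recovery")) {
    for (a in wanted) {
      tr <- truths[[g]][a]
      tr[[a]]$missing_rate <- missing_rate
      groups[[length(groups) + 1]] <- group_spec(
        label = g, n_subjects = sizes[[a]][[g]], analytes = tr)
    }
  }
  cohort_config(groups = groups, seed = seed)
}

#' Assemble a simulation configuration
#'
#' @param groups List of [group_spec()] objects. Several specs may share a
#'   label as long as their analyte sets are disjoint (used when group sizes
#'   differ between analytes).
#' @param schedule Within-day clock times.
#' @param n_days Number of sampling days (2 in the study design).
#' @param seed Integer seed; the seed fully determines the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups, schedule = canonical_schedule(),
                          n_days = 2, seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "group_spec")))
  key <- unlist(lapply(groups, function(g) paste(g$label, names(g$analytes))))
  if (anyDuplicated(key)) {
    stop("duplicate group x analyte specification: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(list(groups = groups, schedule = schedule,
                 n_days = as.integer(n_days), seed = as.integer(seed)),
            class = "cohort_config")
}

#' Simulate one subject's two-day profile
#'
#' The measured value at each scheduled elapsed time is the subject's truth
#' cosinor curve evaluated there, times a multiplicative Gaussian noise
#' factor `1 + e`, `e ~ N(0, noise_cv)`, truncated at 0 to keep
#' concentrations physical; each slot is then independently missing with
#' probability `missing_rate`. Draws come from the current RNG state, so a
#' fixed seed reproduces the profile exactly.
#'
#' @param subject_id,group,analyte Identifiers for the output rows.
#' @param truth List with numeric fields `mesor`, `amplitude`,
#'   `acrophase_clock`, `period` — the subject's generating cosinor curve.
#' @param schedule Within-day clock times.
#' @param noise_cv Fractional coefficient of variation of the multiplicative
#'   noise.
#' @param missing_rate Per-slot missingness probability.
#' @param n_days Number of sampling days.
#' @return A samples tibble (one row per scheduled slot, NA value = missing).
#' @export
simulate_subject <- function(subject_id, group, analyte, truth,
                             schedule = canonical_schedule(),
                             noise_cv = 0, missing_rate = 0, n_days = 2) {
  stopifnot(noise_cv >= 0, missing_rate >= 0, missing_rate < 1)
  grid <- schedule_grid(schedule, n_days)
  curve <- list(mesor = truth$mesor, amplitude = truth$amplitude,
                acrophase_clock = truth$acrophase_clock %% 24,
                period = truth$period, clock_origin = schedule[1],
                phase_elapsed = (truth$acrophase_clock - schedule[1]) %% truth$period)
  mu <- predict_cosinor(curve, grid$elapsed_time, timescale = "elapsed")
  eps <- rnorm(nrow(grid), mean = 0, sd = noise_cv)
  value <- pmax(mu * (1 + eps), 0)
  miss <- runif(nrow(grid)) < missing_rate
  value[miss] <- NA_real_
  tibble::tibble(subject_id = subject_id, group = group, analyte = analyte,
                 day = grid$day, clock_time = grid$clock_time,
                 elapsed_time = grid$elapsed_time, value = value)
}

# Draw one subject's truth parameters from a group's analyte distribution.
# Amplitude is truncated to [0, mesor]: a concentration curve must stay
# non-negative, so a physical cosinor truth has amplitude <= mesor.
draw_truth <- function(spec_a) {
  trunc0 <- function(x) max(x, 0)
  mesor <- trunc0(rnorm(1, spec_a$mesor[1], spec_a$mesor[2]))
  list(
    mesor = mesor,
    amplitude = min(trunc0(rnorm(1, spec_a$amplitude[1], spec_a$amplitude[2])), mesor),
    # wrapped normal on the 24-h clock
    acrophase_clock = rnorm(1, spec_a$acrophase[1], spec_a$acrophase[2]) %% 24,
    period = trunc0(rnorm(1, spec_a$period[1], spec_a$period[2]))
  )
}

#' Simulate a full cohort
#'
#' Draws per-subject truth parameters from each group's distributions and
#' simulates every profile on the configured schedule. Subject ids are
#' `S001, S002, ...` in a deterministic order (groups in configuration
#' order). The configuration seed is applied at entry, so the same
#' configuration always yields byte-identical output.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory; when given, writes `profiles.csv`
#'   (the [read_profiles()] dialect) and `truth.csv` (per-subject generating
#'   parameters).
#' @return A list with `samples` (tibble, schedule attribute set) and
#'   `truth` (tibble: `subject_id`, `group`, `analyte`, `mesor`,
#'   `amplitude`, `acrophase_clock`, `period`, `noise_cv`, `missing_rate`),
#'   plus `paths` when `dir` was given.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  samples <- list()
  truths <- list()
  sid <- 0L
  for (g in config$groups) {
    for (i in seq_len(g$n_subjects)) {
      sid <- sid + 1L
      subject_id <- sprintf("S%03d", sid)
      for (a in names(g$analytes)) {
        spec_a <- g$analytes[[a]]
        tr <- draw_truth(spec_a)
        samples[[length(samples) + 1]] <- simulate_subject(
          subject_id, g$label, a, tr,
          schedule = config$schedule, noise_cv = spec_a$noise_cv,
          missing_rate = spec_a$missing_rate, n_days = config$n_days)
        truths[[length(truths) + 1]] <- tibble::tibble(
          subject_id = subject_id, group = g$label, analyte = a,
          mesor = tr$mesor, amplitude = tr$amplitude,
          acrophase_clock = tr$acrophase_clock, period = tr$period,
          noise_cv = spec_a$noise_cv, missing_rate = spec_a$missing_rate)
      }
    }
  }
  samples <- dplyr::bind_rows(samples)
  samples <- dplyr::arrange(samples, .data$subject_id, .data$analyte,
                            .data$elapsed_time)
  attr(samples, "schedule") <- config$schedule
  truth <- dplyr::bind_rows(truths)
  out <- list(samples = samples, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(profiles = file.path(dir, "profiles.csv"),
                  truth = file.path(dir, "truth.csv"))
    write_profiles(samples, paths$profiles)
    readr::write_csv(truth, paths$truth, na = "")
    out$paths <- paths
  }
  out
}

#' Null version of a configuration
#'
#' Returns a configuration in which every group draws from one shared truth
#' distribution (the first group's), keeping labels and sizes. Used for
#' type-I-error simulations: any detected group difference is then a false
#' positive.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_config` with identical group specs up to label/size.
#' @export
make_null_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  # shared truth per analyte, taken from the first group that carries it
  shared <- list()
  for (g in config$groups) {
    for (a in names(g$analytes)) {
      if (is.null(shared[[a]])) shared[[a]] <- g$analytes[[a]]
    }
  }
  config$groups <- lapply(config$groups, function(g) {
    g$analytes <- shared[names(g$analytes)]
    g
  })
  config
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML path.
#' @param config A [cohort_config()].
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g) {
    analytes <- lapply(g$analytes, function(a) {
      list(mesor = as.numeric(a$mesor), amplitude = as.numeric(a$amplitude),
           acrophase = as.numeric(a$acrophase), period = as.numeric(a$period),
           noise_cv = as.numeric(a$noise_cv),
           missing_rate = as.numeric(a$missing_rate))
    })
    group_spec(g$label, g$n_subjects, analytes)
  })
  cohort_config(groups,
                schedule = if (!is.null(y$schedule)) as.numeric(y$schedule) else canonical_schedule(),
                n_days = if (!is.null(y$n_days)) y$n_days else 2,
                seed = if (!is.null(y$seed)) y$seed else 1L)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- list(
    schedule = config$schedule, n_days = config$n_days, seed = config$seed,
    groups = lapply(config$groups, function(g) {
      list(label = g$label, n_subjects = g$n_subjects, analytes = g$analytes)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
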