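#' Single-component cosinor fitting
#'
#' The rhythm model is the standard single-component cosinor
#' \deqn{Y(t) = M + A \cos\!\big(2\pi (t - \phi) / \lambda\big)}
#' with mesor \eqn{M}, amplitude \eqn{A \ge 0}, acrophase \eqn{\phi} (the
#' time of the fitted maximum) and wavelength (period) \eqn{\lambda}, fixed
#' at 24 h for the primary fits. With the period fixed the model is linear in
#' \eqn{M} and in the rectangular coefficients \eqn{a, b} of
#' \eqn{a\cos\omega t + b\sin\omega t}; `fit_cosinor()` therefore solves
#' ordinary least squares exactly and converts to polar form:
#' \eqn{A = \sqrt{a^2+b^2}}, \eqn{\phi = \mathrm{atan2}(b, a)/\omega}.
#'
#' Fitting runs on the continuous elapsed-time axis (hours since the first
#' scheduled sample; see [elapsed_time()]); the acrophase is reported as the
#' clock time of the curve maximum, in `[0, 24)`. A sine parameterization
#' (`form = "sine"`, conventional for cortisol) is an exact
#' reparameterization of the cosine form — the sine curve peaks a quarter
#' period after its phase parameter — so both forms yield identical
#' canonical results; `form` only records which convention was requested.
#'
#' @param elapsed Numeric vector of elapsed sample times in hours.
#' @param value Numeric vector of concentrations; NA entries are dropped.
#' @param period Fixed period (wavelength) in hours; 24 for the primary fit.
#' @param form `"cosine"` or `"sine"`; recorded in the result, does not
#'   change the fitted curve.
#' @param clock_origin Clock time corresponding to `elapsed = 0` (08:00 for
#'   the canonical schedule).
#' @return An object of class `cosinor_fit`: a list with elements `mesor`,
#'   `amplitude`, `acrophase_clock`, `period`, `r_squared`, `form`,
#'   `period_mode`, `n_used`, `sse`, `degenerate` (logical: amplitude
#'   indistinguishable from zero, acrophase undefined and reported NA) and
#'   `clock_origin`.
#' @examples
#' sched <- schedule_grid()
#' y <- 10 + 5 * cos(2 * pi * (sched$elapsed_time - 0) / 24)  # peak at 08:00
#' fit <- fit_cosinor(sched$elapsed_time, y)
#' fit$acrophase_clock  # 8
#' @export
fit_cosinor <- function(elapsed, value, period = 24, form = c("cosine", "sine"),
                        clock_origin = canonical_schedule()[1]) {
  form <- match.arg(form)
  stopifnot(length(elapsed) == length(value), period > 0)
  keep <- !is.na(value) & !is.na(elapsed)
  t <- elapsed[keep]
  y <- value[keep]
  n <- length(y)
  if (n < 4) stop("cosinor fit needs at least 4 non-missing points, got ", n)

  omega <- 2 * pi / period
  X <- cbind(1, cos(omega * t), sin(omega * t))
  co <- .lm.fit(X, y)$coefficients
  mesor <- co[1]
  a <- co[2]
  b <- co[3]
  amplitude <- sqrt(a^2 + b^2)
  # peak of a*cos + b*sin at omega*t = atan2(b, a)
  phase_elapsed <- (atan2(b, a) / omega) %% period

  fitted <- X %*% co
  sse <- sum((y - fitted)^2)
  sstot <- sum((y - mean(y))^2)
  r_squared <- if (sstot > 0) 1 - sse / sstot else NA_real_

  degenerate <- amplitude <= 1e-8 * max(abs(mesor), 1e-12)
  if (degenerate) {
    amplitude <- 0
    acrophase_clock <- NA_real_
    phase_elapsed <- NA_real_
  } else {
    acrophase_clock <- (clock_origin + phase_elapsed) %% 24
  }

  structure(
    list(mesor = mesor, amplitude = amplitude,
         acrophase_clock = acrophase_clock, phase_elapsed = phase_elapsed,
         period = period,
         r_squared = r_squared, form = form, period_mode = "fixed",
         n_used = n, sse = sse, degenerate = degenerate,
         clock_origin = clock_origin),
    class = "cosinor_fit"
  )
}

#' Iterative cosinor fitting with fixed or bounded free period
#'
#' `fit_cosinor_nls()` refines the closed-form solution by iterative least
#' squares. In `"fixed24"` mode the period stays at `period` and the result
#' coincides with [fit_cosinor()] (same objective, exact start). In
#' `"free_bounded"` mode the period is itself estimated within
#' `period_bounds` by profiling: for each candidate period the conditionally
#' optimal mesor/amplitude/acrophase come from the closed form, and the
#' profiled sum of squares is minimized over the period by a grid scan
#' followed by golden-section refinement. The free-period sum of squares is
#' never above the fixed-period one (the fixed period is a candidate).
#'
#' @inheritParams fit_cosinor
#' @param period_mode `"fixed24"` or `"free_bounded"`.
#' @param period_bounds Length-2 numeric, the allowed period range in hours
#'   for `"free_bounded"` mode.
#' @return A `cosinor_fit`; in free mode `period_mode = "free"` and the
#'   element `at_bound` flags an optimum on the boundary.
#' @export
fit_cosinor_nls <- function(elapsed, value, period = 24,
                            period_mode = c("fixed24", "free_bounded"),
                            period_bounds = c(20, 28),
                            form = c("cosine", "sine"),
                            clock_origin = canonical_schedule()[1]) {
  period_mode <- match.arg(period_mode)
  form <- match.arg(form)
  keep <- !is.na(value) & !is.na(elapsed)
  t <- elapsed[keep]
  y <- value[keep]

  if (period_mode == "fixed24") {
    start <- fit_cosinor(t, y, period = period, form = form,
                         clock_origin = clock_origin)
    if (start$degenerate) return(start)
    ref <- refine_cosinor_nls(t, y, start, period = period)
    ref$form <- form
    return(ref)
  }

  if (length(y) < 5) stop("free-period fit needs at least 5 non-missing points")
  stopifnot(length(period_bounds) == 2, diff(period_bounds) > 0)

  # profiled SSE: with the period held, the conditional optimum is linear OLS
  prof_sse <- function(p) {
    w <- 2 * pi / p
    r <- .lm.fit(cbind(1, cos(w * t), sin(w * t)), y)$residuals
    sum(r^2)
  }
  grid <- seq(period_bounds[1], period_bounds[2], by = 0.25)
  sses <- vapply(grid, prof_sse, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(prof_sse, lower = lo, upper = hi, tol = 1e-8)
  # keep whichever candidate truly minimizes (optimize can miss a boundary)
  cand <- c(opt$minimum, grid[i], period_bounds)
  best_p <- cand[which.min(vapply(cand, prof_sse, numeric(1)))]

  fit <- fit_cosinor(t, y, period = best_p, form = form,
                     clock_origin = clock_origin)
  fit$period_mode <- "free"
  fit$at_bound <- any(abs(best_p - period_bounds) < 1e-6)
  if (fit$at_bound) {
    warning("free-period optimum at bound (", signif(best_p, 6), " h)")
  }
  fit
}

# Gauss-Newton polish in (mesor, amplitude, acrophase) via minpack.lm,
# started at the closed-form optimum; falls back to the start on failure.
refine_cosinor_nls <- function(t, y, start, period) {
  omega <- 2 * pi / period
  phi0 <- ((start$acrophase_clock - start$clock_origin) %% 24)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ M + A * cos(omega * (t - phi)),
      data = df,
      start = list(M = start$mesor, A = start$amplitude, phi = phi0),
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(start)
  p <- coef(fit)
  out <- canonicalize_cosinor(
    mesor = p[["M"]], amplitude = p[["A"]],
    phase = p[["phi"]], form = "cosine", period = period,
    phase_is_clock = FALSE, clock_origin = start$clock_origin
  )
  sse <- sum(stats::residuals(fit)^2)
  if (sse > start$sse * (1 + 1e-12) + 1e-12) return(start)
  start$mesor <- out$mesor
  start$amplitude <- out$amplitude
  start$acrophase_clock <- out$acrophase_clock
  start$phase_elapsed <- (out$acrophase_clock - start$clock_origin) %% period
  start$sse <- sse
  sstot <- sum((y - mean(y))^2)
  start$r_squared <- if (sstot > 0) 1 - sse / sstot else NA_real_
  start
}

#' Canonicalize cosinor parameters
#'
#' Reduces any sign/phase representation of a single-component cosinor to
#' the canonical one: amplitude non-negative and acrophase reported as the
#' clock time of the curve maximum in `[0, 24)`. A negative amplitude shifts
#' the peak by half a period; a sine-form phase parameter is converted using
#' the identity that the sine curve peaks a quarter period after its phase.
#'
#' @param mesor Mesor.
#' @param amplitude Amplitude, any sign.
#' @param phase Phase parameter of the given `form`, any real value, in
#'   hours. By default interpreted as a clock time; set
#'   `phase_is_clock = FALSE` for a phase on the elapsed axis.
#' @param form `"cosine"` (peak at the phase) or `"sine"` (peak a quarter
#'   period after the phase).
#' @param period Period in hours.
#' @param phase_is_clock Whether `phase` is on the clock axis.
#' @param clock_origin Clock time of elapsed 0, used when
#'   `phase_is_clock = FALSE`.
#' @return A list with `mesor`, `amplitude` (>= 0) and `acrophase_clock` in
#'   `[0, 24)`.
#' @examples
#' canonicalize_cosinor(10, -3, 10, form = "cosine")  # amplitude 3, peak 22
#' canonicalize_cosinor(10, 5, 2, form = "sine")      # sine peak = 2 + 6 = 8
#' @export
canonicalize_cosinor <- function(mesor, amplitude, phase,
                                 form = c("cosine", "sine"), period = 24,
                                 phase_is_clock = TRUE,
                                 clock_origin = canonical_schedule()[1]) {
  form <- match.arg(form)
  peak <- phase
  if (form == "sine") peak <- peak + period / 4
  if (amplitude < 0) {
    amplitude <- -amplitude
    peak <- peak + period / 2
  }
  if (!phase_is_clock) peak <- clock_origin + (peak %% period)
  list(mesor = mesor, amplitude = amplitude,
       acrophase_clock = peak %% 24)
}

#' Evaluate a fitted cosinor curve
#'
#' Evaluates `mesor + amplitude * cos(2*pi*(t - acrophase_clock)/period)`.
#' Times may be given as clock hours (default) or as elapsed hours, which
#' are first mapped to clock time through the fit's clock origin; for the
#' 24-h primary fits the two give identical values.
#'
#' @param object A `cosinor_fit` (or any list with `mesor`, `amplitude`,
#'   `acrophase_clock`, `period`, and `clock_origin` fields).
#' @param times Numeric times in hours.
#' @param timescale `"clock"` or `"elapsed"`.
#' @return Numeric vector of fitted concentrations.
#' @examples
#' fit <- list(mesor = 10, amplitude = 5, acrophase_clock = 8, period = 24,
#'             clock_origin = 8)
#' predict_cosinor(fit, c(8, 20, 2))  # 15, 5, 10
#' @export
predict_cosinor <- function(object, times, timescale = c("clock", "elapsed")) {
  timescale <- match.arg(timescale)
  if (timescale == "elapsed") {
    if (!is.null(object$phase_elapsed) && !is.na(object$phase_elapsed)) {
      return(object$mesor + object$amplitude *
               cos(2 * pi * (times - object$phase_elapsed) / object$period))
    }
    origin <- if (!is.null(object$clock_origin)) object$clock_origin else canonical_schedule()[1]
    times <- origin + times
  }
  if (is.na(object$acrophase_clock)) {
    return(rep(object$mesor, length(times)))
  }
  object$mesor + object$amplitude *
    cos(2 * pi * (times - object$acrophase_clock) / object$period)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (%s, period %s): mesor %.4g, amplitude %.4g, acrophase %s, R^2 %.3f, n %d\n",
    x$form, if (x$period_mode == "free") sprintf("%.2f h (free)", x$period) else sprintf("%g h", x$period),
    x$mesor, x$amplitude,
    if (is.na(x$acrophase_clock)) "undefined" else sprintf("%.2f h clock", x$acrophase_clock),
    x$r_squared, x$n_used))
  invisible(x)
}

#' Fit both cosinor variants for every profile in a cohort
#'
#' Runs the fixed-24 fit (the source of acrophase, fitted peak and mesor)
#' and the bounded free-period fit (the source of the period feature) for
#' each subject x analyte series. Cortisol fits are recorded in the sine
#' parameterization and melatonin in the cosine one, matching the reporting
#' convention for each hormone; the canonical parameters are identical
#' either way.
#'
#' @param samples A samples tibble from [read_profiles()] or
#'   [simulate_cohort()].
#' @param period_bounds Allowed free-period range in hours.
#' @param min_points Minimum non-missing points for a fixed fit (the free
#'   fit needs one more).
#' @return A tibble with one row per subject x analyte and columns
#'   `subject_id`, `group`, `analyte`, `form`, `mesor`, `amplitude`,
#'   `acrophase_clock`, `r_squared`, `sse`, `n_used`, `degenerate`,
#'   `period_free`, `sse_free`, `period_at_bound`, and `fit_ok`.
#' @export
cosinor_fit_table <- function(samples, period_bounds = c(20, 28), min_points = 4) {
  origin <- attr(samples, "schedule")
  origin <- if (is.null(origin)) canonical_schedule()[1] else origin[1]
  keys <- dplyr::distinct(samples, .data$subject_id, .data$group, .data$analyte)
  n <- nrow(keys)
  col_num <- function() rep(NA_real_, n)
  out <- list(mesor = col_num(), amplitude = col_num(),
              acrophase_clock = col_num(), r_squared = col_num(),
              sse = col_num(), n_used = rep(NA_integer_, n),
              degenerate = rep(NA, n), period_free = col_num(),
              sse_free = col_num(), period_at_bound = rep(NA, n),
              fit_ok = rep(FALSE, n))
  skey <- paste(samples$subject_id, samples$analyte, sep = "\r")
  for (i in seq_len(n)) {
    sub <- samples[skey == paste(keys$subject_id[i], keys$analyte[i], sep = "\r"), ]
    form <- if (keys$analyte[i] == "cortisol") "sine" else "cosine"
    n_ok <- sum(!is.na(sub$value))
    out$n_used[i] <- n_ok
    if (n_ok < min_points) next
    fx <- fit_cosinor(sub$elapsed_time, sub$value, period = 24, form = form,
                      clock_origin = origin)
    out$mesor[i] <- fx$mesor
    out$amplitude[i] <- fx$amplitude
    out$acrophase_clock[i] <- fx$acrophase_clock
    out$r_squared[i] <- fx$r_squared
    out$sse[i] <- fx$sse
    out$degenerate[i] <- fx$degenerate
    out$fit_ok[i] <- TRUE
    if (n_ok >= min_points + 1 && !fx$degenerate) {
      ff <- withCallingHandlers(
        fit_cosinor_nls(sub$elapsed_time, sub$value,
                        period_mode = "free_bounded",
                        period_bounds = period_bounds, form = form,
                        clock_origin = origin),
        warning = function(w) invokeRestart("muffleWarning")
      )
      out$period_free[i] <- ff$period
      out$sse_free[i] <- ff$sse
      out$period_at_bound[i] <- isTRUE(ff$at_bound)
    }
  }
  tibble::tibble(
    subject_id = keys$subject_id, group = keys$group, analyte = keys$analyte,
    form = ifelse(keys$analyte == "cortisol", "sine", "cosine"),
    mesor = out$mesor, amplitude = out$amplitude,
    acrophase_clock = out$acrophase_clock, r_squared = out$r_squared,
    sse = out$sse, n_used = out$n_used, degenerate = out$degenerate,
    period_free = out$period_free, sse_free = out$sse_free,
    period_at_bound = out$period_at_bound, fit_ok = out$fit_ok
  )
}
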