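#' Clock time to phase angle and back
#'
#' A 24-h clock is mapped to the unit circle with midnight (00:00) at angle
#' 0 and angles increasing through the day: `angle = 2*pi*clock/24`. The
#' inverse maps an angle (any real value) back to clock hours in `[0, 24)`.
#'
#' @param clock_time Clock hours in `[0, 24)`.
#' @param angle Angle in radians.
#' @return Radians in `[0, 2*pi)`, or clock hours in `[0, 24)`.
#' @examples
#' phase_angle(6)            # pi/2
#' clock_of_angle(3 * pi / 2)  # 18
#' @export
phase_angle <- function(clock_time) {
  stopifnot(all(clock_time >= 0 & clock_time < 24))
  2 * pi * clock_time / 24
}

#' @rdname phase_angle
#' @export
clock_of_angle <- function(angle) {
  (angle * 24 / (2 * pi)) %% 24
}

#' Mean resultant vector of a set of phase angles
#'
#' The rectangular mean of the unit vectors (optionally weighted): the mean
#' direction is `atan2` of the mean sine and cosine and the resultant length
#' is the norm of that mean, 1 for perfect phase agreement and 0 for
#' complete dispersion. With a resultant length numerically indistinguishable
#' from 0 the mean direction is undefined and reported NA.
#'
#' @param angles Numeric vector of angles in radians, length >= 1.
#' @param weights Optional non-negative weights (e.g. per-subject fit
#'   strength), same length, not all zero.
#' @return A list of class `circular_summary`: `n`, `mean_angle` (radians in
#'   `[0, 2*pi)` or NA), `resultant_length`, `mean_clock` (hours or NA),
#'   `weights_used`.
#' @export
mean_vector <- function(angles, weights = NULL) {
  if (length(angles) < 1) stop("mean_vector needs at least one angle")
  if (is.null(weights)) {
    w <- rep(1, length(angles))
    weights_used <- FALSE
  } else {
    stopifnot(length(weights) == length(angles), all(weights >= 0))
    if (sum(weights) == 0) stop("weights must not all be zero")
    w <- weights
    weights_used <- TRUE
  }
  w <- w / sum(w)
  C <- sum(w * cos(angles))
  S <- sum(w * sin(angles))
  R <- sqrt(C^2 + S^2)
  mean_angle <- if (R < 1e-12) NA_real_ else atan2(S, C) %% (2 * pi)
  structure(
    list(n = length(angles), mean_angle = mean_angle, resultant_length = R,
         mean_clock = if (is.na(mean_angle)) NA_real_ else clock_of_angle(mean_angle),
         weights_used = weights_used),
    class = "circular_summary"
  )
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf("circular summary: n %d, mean clock %s, resultant length %.3f%s\n",
              x$n,
              if (is.na(x$mean_clock)) "undefined" else sprintf("%.2f h", x$mean_clock),
              x$resultant_length,
              if (x$weights_used) " (weighted)" else ""))
  invisible(x)
}

# Maximum-likelihood approximation of the von Mises concentration kappa
# from a mean resultant length, by the standard three-regime formula
# (regime boundaries 0.53 and 0.85).
kappa_from_rbar <- function(rbar) {
  if (rbar < 0) rbar <- 0
  if (rbar >= 1) return(Inf)
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Watson-Williams F test for equal mean directions
#'
#' The circular analogue of one-way ANOVA. With per-group resultant lengths
#' \eqn{R_i} (unnormalized), pooled resultant \eqn{R} and \eqn{k} groups of
#' total size \eqn{N}, the statistic is
#' \deqn{F = K \, \frac{(N - k)\,(\sum R_i - R)}{(k - 1)\,(N - \sum R_i)}}
#' with the concentration correction \eqn{K = 1 + 3/(8\hat\kappa)}, where
#' \eqn{\hat\kappa} is estimated from the mean resultant length
#' \eqn{\bar R_w = \sum R_i / N}. The p-value comes from the F distribution
#' with \eqn{(k - 1, N - k)} degrees of freedom. The test assumes von Mises
#' samples with a common, reasonably large concentration; a warning flag is
#' set when \eqn{\hat\kappa < 2}.
#'
#' @param groups A list of numeric vectors of angles in radians, one per
#'   group; at least 2 groups, each of size >= 2.
#' @return A list of class `watson_williams`: `F_statistic`, `df_between`,
#'   `df_within`, `p_value`, `kappa_hat`, `assumption_warning`, plus the
#'   per-group summaries `n_per_group`, `mean_clock_per_group`,
#'   `resultant_per_group` (normalized).
#' @export
watson_williams <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("watson_williams needs a list of at least two groups")
  }
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs at least 2 angles")
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    stop("angles must be finite")
  }
  k <- length(groups)
  N <- sum(ns)
  Ci <- vapply(groups, function(g) sum(cos(g)), numeric(1))
  Si <- vapply(groups, function(g) sum(sin(g)), numeric(1))
  Ri <- sqrt(Ci^2 + Si^2)
  R <- sqrt(sum(Ci)^2 + sum(Si)^2)
  sumRi <- sum(Ri)
  if (N - sumRi < 1e-12) {
    stop("degenerate within-group dispersion: all angles (essentially) identical")
  }
  rbar_w <- sumRi / N
  kappa_hat <- kappa_from_rbar(rbar_w)
  K <- 1 + 3 / (8 * kappa_hat)
  F_statistic <- K * (N - k) * (sumRi - R) / ((k - 1) * (N - sumRi))
  F_statistic <- max(F_statistic, 0)
  p_value <- pf(F_statistic, k - 1, N - k, lower.tail = FALSE)
  structure(
    list(F_statistic = F_statistic, df_between = k - 1L, df_within = N - k,
         p_value = p_value, kappa_hat = kappa_hat,
         assumption_warning = kappa_hat < 2,
         n_per_group = ns,
         mean_clock_per_group = vapply(groups, function(g) mean_vector(g)$mean_clock, numeric(1)),
         resultant_per_group = Ri / ns),
    class = "watson_williams"
  )
}

#' @export
print.watson_williams <- function(x, ...) {
  cat(sprintf("Watson-Williams F test: F(%d, %d) = %.4f, p = %.4g, kappa_hat = %.2f%s\n",
              x$df_between, x$df_within, x$F_statistic, x$p_value, x$kappa_hat,
              if (x$assumption_warning) " [low-concentration warning]" else ""))
  invisible(x)
}

#' Rayleigh test of angular uniformity
#'
#' Tests whether phases are uniformly distributed on the circle using
#' `z = n * R^2` with `R` the mean resultant length; the p-value uses the
#' standard small-sample series approximation
#' `p = exp(-z) * (1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288 n^2))`,
#' clamped to `[0, 1]`.
#'
#' @param angles Numeric vector of angles in radians, n >= 3.
#' @return A list with `z_statistic`, `p_value`, `n`, `resultant_length`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3) stop("rayleigh_test needs at least 3 angles")
  R <- mean_vector(angles)$resultant_length
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z_statistic = z, p_value = min(max(p, 0), 1), n = n, resultant_length = R)
}

#' Circular comparison table for group acrophases
#'
#' Runs the Watson-Williams test for each requested pairing on the fitted
#' acrophases (degenerate/undefined acrophases are dropped) and summarizes
#' each group's mean vector.
#'
#' @param fits Fit table from [cosinor_fit_table()].
#' @param pairings List of 2-character vectors of group labels.
#' @return A tibble, one row per analyte x pairing, with per-group n, mean
#'   clock and resultant length, F, dfs, p and the assumption flag. Pairings
#'   with a group below 2 usable angles are marked not computable.
#' @export
circular_comparison_table <- function(fits,
                                      pairings = list(c("control", "depression"),
                                                      c("control", "recovery"))) {
  rows <- list()
  for (analyte in unique(fits$analyte)) {
    fa <- fits[fits$analyte == analyte & !is.na(fits$acrophase_clock), ]
    for (pair in pairings) {
      a <- fa$acrophase_clock[fa$group == pair[1]]
      b <- fa$acrophase_clock[fa$group == pair[2]]
      base <- tibble::tibble(
        analyte = analyte, group_a = pair[1], group_b = pair[2],
        n_a = length(a), n_b = length(b),
        mean_clock_a = NA_real_, mean_clock_b = NA_real_,
        resultant_a = NA_real_, resultant_b = NA_real_,
        F_statistic = NA_real_, df_between = NA_integer_,
        df_within = NA_integer_, p_value = NA_real_,
        kappa_hat = NA_real_, assumption_warning = NA, computable = FALSE
      )
      if (length(a) >= 1) {
        mv <- mean_vector(phase_angle(a))
        base$mean_clock_a <- mv$mean_clock
        base$resultant_a <- mv$resultant_length
      }
      if (length(b) >= 1) {
        mv <- mean_vector(phase_angle(b))
        base$mean_clock_b <- mv$mean_clock
        base$resultant_b <- mv$resultant_length
      }
      if (length(a) >= 2 && length(b) >= 2) {
        ww <- tryCatch(watson_williams(list(phase_angle(a), phase_angle(b))),
                       error = function(e) NULL)
        if (!is.null(ww)) {
          base$F_statistic <- ww$F_statistic
          base$df_between <- ww$df_between
          base$df_within <- ww$df_within
          base$p_value <- ww$p_value
          base$kappa_hat <- ww$kappa_hat
          base$assumption_warning <- ww$assumption_warning
          base$computable <- TRUE
        }
      }
      rows[[length(rows) + 1]] <- base
    }
  }
  dplyr::bind_rows(rows)
}

#' Circular difference between two clock times
#'
#' Signed shortest difference `a - b` on the 24-h circle, in hours, in
#' `(-12, 12]`. Positive means `a` is later than `b`.
#'
#' @param a,b Clock hours.
#' @return Signed hours.
#' @examples
#' clock_difference(3, 23)  # 4, not -20
#' @export
clock_difference <- function(a, b) {
  d <- (a - b) %% 24
  ifelse(d > 12, d - 24, d)
}
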