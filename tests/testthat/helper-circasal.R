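# Shared fixtures and independent oracles for the test suite.

# Build a samples tibble for one subject x analyte from a value vector of
# length 14 (canonical two-day grid order); NA = missing.
make_profile <- function(values, subject_id = "S1", group = "control",
                         analyte = "cortisol") {
  grid <- circasal:::schedule_grid()
  stopifnot(length(values) == nrow(grid))
  tibble::tibble(subject_id = subject_id, group = group, analyte = analyte,
                 day = grid$day, clock_time = grid$clock_time,
                 elapsed_time = grid$elapsed_time, value = values)
}

# Noiseless cosinor values on the canonical grid (clock-time acrophase).
cosinor_values <- function(mesor, amplitude, acrophase_clock, period = 24) {
  grid <- circasal:::schedule_grid()
  mesor + amplitude * cos(2 * pi * (grid$elapsed_time - ((acrophase_clock - 8) %% period)) / period)
}

# Random noisy two-day profile (values and elapsed times), for oracle tests.
random_profile <- function(mesor = NULL, amplitude = NULL, acro = NULL,
                           sd = 0.5) {
  grid <- circasal:::schedule_grid()
  if (is.null(mesor)) mesor <- runif(1, 5, 15)
  if (is.null(amplitude)) amplitude <- runif(1, 1, 8)
  if (is.null(acro)) acro <- runif(1, 0, 24)
  y <- mesor + amplitude * cos(2 * pi * (grid$elapsed_time - ((acro - 8) %% 24)) / 24) +
    rnorm(nrow(grid), 0, sd)
  list(t = grid$elapsed_time, y = y,
       truth = list(mesor = mesor, amplitude = amplitude, acrophase_clock = acro))
}

# --- Independent oracles -----------------------------------------------------

# Brute-force cosinor: iteratively refined grid search over
# (mesor, amplitude, acrophase), no linear algebra shared with the package.
grid_search_cosinor <- function(t, y, period = 24, clock_origin = 8) {
  sse_of <- function(m, a, phi) {
    sum((y - (m + a * cos(2 * pi * (t - phi) / period)))^2)
  }
  m_rng <- range(y)
  a_rng <- c(0, diff(range(y)))
  p_rng <- c(0, period)
  best <- c(mean(y), diff(range(y)) / 2, period / 2)
  for (pass in 1:8) {
    ms <- seq(m_rng[1], m_rng[2], length.out = 11)
    as <- seq(a_rng[1], a_rng[2], length.out = 11)
    ps <- seq(p_rng[1], p_rng[2], length.out = 25)
    best_sse <- Inf
    for (m in ms) for (a in as) for (p in ps) {
      s <- sse_of(m, a, p)
      if (s < best_sse) { best_sse <- s; best <- c(m, a, p) }
    }
    shrink <- function(rng, centre) {
      w <- diff(rng) / 4
      c(centre - w, centre + w)
    }
    m_rng <- shrink(m_rng, best[1])
    a_rng <- pmax(shrink(a_rng, best[2]), 0)
    p_rng <- shrink(p_rng, best[3])
  }
  list(mesor = best[1], amplitude = best[2],
       acrophase_clock = (clock_origin + best[3]) %% 24,
       sse = sse_of(best[1], best[2], best[3]))
}

# Textbook Watson-Williams evaluation, written line by line.
ww_oracle <- function(groups) {
  k <- length(groups)
  N <- sum(lengths(groups))
  Ri <- numeric(k)
  Csum <- 0
  Ssum <- 0
  for (i in seq_len(k)) {
    Ci <- sum(cos(groups[[i]]))
    Si <- sum(sin(groups[[i]]))
    Ri[i] <- sqrt(Ci^2 + Si^2)
    Csum <- Csum + Ci
    Ssum <- Ssum + Si
  }
  R <- sqrt(Csum^2 + Ssum^2)
  rw <- sum(Ri) / N
  kappa <- if (rw < 0.53) {
    2 * rw + rw^3 + 5 * rw^5 / 6
  } else if (rw < 0.85) {
    -0.4 + 1.39 * rw + 0.43 / (1 - rw)
  } else {
    1 / (rw^3 - 4 * rw^2 + 3 * rw)
  }
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  list(F = Fstat, p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Pooled-variance two-sample t, direct formula.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# von Mises sampler (Best & Fisher 1979 rejection scheme).
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- (mu + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# Tiny two-group melatonin configuration used by several simulation tests.
two_group_melatonin_config <- function(seed = 1L, missing_rate = 0.05) {
  tr <- function(acro) list(
    mesor = c(12, 2.5), amplitude = c(10, 2.5), acrophase = c(acro, 1),
    period = c(24, 0), noise_cv = 0.108, missing_rate = missing_rate)
  cohort_config(list(
    group_spec("control", 12, list(melatonin = tr(3.83))),
    group_spec("depression", 8, list(melatonin = tr(1.5)))
  ), seed = seed)
}
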