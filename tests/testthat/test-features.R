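test_that("two-day difference is zero on duplicated days and |c| under a day-2 offset", {
  vals <- cosinor_values(10, 5, 8)
  dup <- vals
  dup[8:14] <- dup[1:7]
  f <- extract_features(make_profile(dup))
  expect_equal(f$two_day_diff, 0)

  off <- dup
  off[8:14] <- off[1:7] - 1.7
  f <- extract_features(make_profile(off))
  expect_equal(f$two_day_diff, 1.7)

  # symmetric in the two days, invariant to a shared constant
  both <- dup
  both <- both + 3.2
  expect_equal(extract_features(make_profile(both))$two_day_diff, 0)
})

test_that("daytime slope of an exact line is recovered", {
  vals <- rep(NA_real_, 14)
  vals[1:3] <- c(6, 4, 2)  # clock 8, 11, 14 on day 1
  vals[4:7] <- 1           # fill so the profile is mostly present
  vals[8:14] <- 1
  f <- extract_features(make_profile(vals))
  expect_equal(f$slope_day1, -2 / 3)
})

test_that("slopes scale with the values and ignore additive constants", {
  withr::local_seed(31)
  vals <- cosinor_values(10, 5, 8) + rnorm(14, 0, 0.5)
  base <- extract_features(make_profile(vals))
  scaled <- extract_features(make_profile(vals * 3))
  shifted <- extract_features(make_profile(vals + 11))
  for (s in c("slope_day1", "slope_day2", "slope_night1", "slope_night2")) {
    expect_equal(scaled[[s]], base[[s]] * 3, tolerance = 1e-12)
    expect_equal(shifted[[s]], base[[s]], tolerance = 1e-9)
  }
})

test_that("the anchored maximum is the anchor-slot measurement, not the empirical max", {
  vals <- cosinor_values(10, 5, 8)
  vals[1] <- 99  # day-1 08:00 spike must not leak into max_level
  p <- make_profile(vals, analyte = "cortisol")
  f <- extract_features(p)
  expect_equal(f$max_level, vals[8])   # day-2 08:00
  expect_equal(f$range, 99 - min(vals))

  pm <- make_profile(vals, analyte = "melatonin")
  fm <- extract_features(pm)
  expect_equal(fm$max_level, vals[14])  # day-2 05:00

  # anchor missing -> feature missing, flagged
  vals[8] <- NA
  f2 <- extract_features(make_profile(vals, analyte = "cortisol"))
  expect_true(is.na(f2$max_level))
  expect_match(f2$flags, "anchor_missing")
})

test_that("for a noiseless profile the anchored maximum equals the fitted curve there", {
  vals <- cosinor_values(8, 4, 8)
  p <- make_profile(vals, analyte = "cortisol")
  fit <- fit_cosinor(p$elapsed_time, p$value)
  f <- extract_features(p, fit_fixed = fit)
  expect_equal(f$max_level, predict_cosinor(fit, 24, timescale = "elapsed"),
               tolerance = 1e-12)
  expect_equal(f$fitted_peak, fit$mesor + fit$amplitude)
  expect_gte(f$fitted_peak, f$fitted_mesor)
})

test_that("all twelve features of a seeded cortisol subject match a hand recomputation", {
  withr::local_seed(41)
  vals <- pmax(cosinor_values(4, 3.5, 8) * (1 + rnorm(14, 0, 0.061)), 0)
  p <- make_profile(vals, analyte = "cortisol")
  fits <- cosinor_fit_table(p)
  f <- feature_table(p, fits)

  # independent recomputation from the raw 14 numbers
  t14 <- circasal:::schedule_grid()$elapsed_time
  co <- coef(lm(vals ~ cos(2 * pi * t14 / 24) + sin(2 * pi * t14 / 24)))
  amp <- sqrt(co[2]^2 + co[3]^2)
  acro <- (8 + (atan2(co[3], co[2]) * 24 / (2 * pi)) %% 24) %% 24
  expect_equal(f$fitted_mesor, unname(co[1]), tolerance = 1e-9)
  expect_equal(f$fitted_peak, unname(co[1] + amp), tolerance = 1e-9)
  expect_lt(abs(clock_difference(f$acrophase_clock, acro)), 1e-9)

  sse_p <- function(P) {
    sum(resid(lm(vals ~ cos(2 * pi * t14 / P) + sin(2 * pi * t14 / P)))^2)
  }
  ps <- seq(20, 28, by = 0.001)
  expect_equal(f$period, ps[which.min(vapply(ps, sse_p, numeric(1)))],
               tolerance = 2e-3)

  expect_equal(f$avg_24h, mean(vals))
  expect_equal(f$max_level, vals[8])
  expect_equal(f$range, max(vals) - min(vals))
  expect_equal(f$two_day_diff, mean(abs(vals[1:7] - vals[8:14])))
  expect_equal(f$slope_day1, unname(coef(lm(vals[1:3] ~ c(0, 3, 6)))[2]))
  expect_equal(f$slope_day2, unname(coef(lm(vals[8:10] ~ c(24, 27, 30)))[2]))
  expect_equal(f$slope_night1, unname(coef(lm(vals[c(6, 7, 8)] ~ c(17, 21, 24)))[2]))
  # cortisol night 2 has no third-morning 08:00: two-point slope, flagged
  expect_equal(f$slope_night2, (vals[14] - vals[13]) / 4)
  expect_match(f$flags, "slope_night2_2pt")
})

test_that("melatonin night slopes use the 22:00-01:00-05:00 triplet on both nights", {
  withr::local_seed(43)
  vals <- pmax(cosinor_values(12, 10, 4) * (1 + rnorm(14, 0, 0.108)), 0)
  f <- extract_features(make_profile(vals, analyte = "melatonin"))
  expect_equal(f$slope_night1, unname(coef(lm(vals[5:7] ~ c(14, 17, 21)))[2]))
  expect_equal(f$slope_night2, unname(coef(lm(vals[12:14] ~ c(38, 41, 45)))[2]))
  expect_false(grepl("slope_night2_2pt", f$flags))
})

test_that("sparse slope triplets degrade to two points or go missing", {
  vals <- cosinor_values(10, 5, 8)
  vals[2] <- NA  # day-1 11:00
  f <- extract_features(make_profile(vals))
  expect_equal(f$slope_day1, (vals[3] - vals[1]) / 6)
  expect_match(f$flags, "slope_day1_2pt")
  vals[3] <- NA
  f <- extract_features(make_profile(vals))
  expect_true(is.na(f$slope_day1))
  expect_match(f$flags, "slope_day1_missing")
})

test_that("feature_table has one row per series with missing propagation", {
  cfg <- default_cohort_config(seed = 5)
  sim <- simulate_cohort(cfg)
  keep <- sim$samples$subject_id %in% sprintf("S%03d", 1:3)
  samples <- sim$samples[keep, ]
  fits <- cosinor_fit_table(samples)
  ft <- feature_table(samples, fits)
  expect_equal(nrow(ft), nrow(dplyr::distinct(samples, subject_id, analyte)))
  expect_true(all(feature_names() %in% names(ft)))

  # a series without a free-period fit gets an empty period feature
  fits2 <- fits
  fits2$period_free[1] <- NA
  ft2 <- feature_table(samples, fits2)
  expect_true(is.na(ft2$period[1]))

  # fits for an unknown subject are a consistency error
  bad <- fits
  bad$subject_id[1] <- "GHOST"
  expect_error(feature_table(samples, bad), "absent from the profiles")
})
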