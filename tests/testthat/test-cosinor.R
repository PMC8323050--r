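test_that("noiseless profiles are recovered exactly by the closed form", {
  grid <- circasal:::schedule_grid()
  for (acro in c(0.5, 8, 13.7, 23.2)) {
    y <- cosinor_values(10, 5, acro)
    fit <- fit_cosinor(grid$elapsed_time, y)
    expect_equal(fit$mesor, 10, tolerance = 1e-9)
    expect_equal(fit$amplitude, 5, tolerance = 1e-9)
    expect_lt(abs(clock_difference(fit$acrophase_clock, acro)), 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$n_used, 14)
  }
})

test_that("a constant profile yields zero amplitude and an undefined acrophase", {
  grid <- circasal:::schedule_grid()
  fit <- fit_cosinor(grid$elapsed_time, rep(7.2, 14))
  expect_equal(fit$mesor, 7.2)
  expect_identical(fit$amplitude, 0)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$acrophase_clock))
  expect_true(is.na(fit$r_squared))
})

test_that("too few points raise an insufficient-data error", {
  expect_error(fit_cosinor(c(0, 3, 6), c(1, 2, 3)), "at least 4")
  y <- cosinor_values(10, 5, 8)
  y[4:14] <- NA
  expect_error(fit_cosinor(circasal:::schedule_grid()$elapsed_time, y), "at least 4")
  expect_error(
    fit_cosinor_nls(c(0, 3, 6, 11), c(1, 2, 3, 2), period_mode = "free_bounded"),
    "at least 5"
  )
})

test_that("the closed form matches a brute-force grid-search oracle", {
  withr::local_seed(101)
  prof <- random_profile()
  fit <- fit_cosinor(prof$t, prof$y)
  oracle <- grid_search_cosinor(prof$t, prof$y)
  expect_equal(fit$mesor, oracle$mesor, tolerance = 1e-3)
  expect_equal(fit$amplitude, oracle$amplitude, tolerance = 1e-3)
  expect_lt(abs(clock_difference(fit$acrophase_clock, oracle$acrophase_clock)), 1e-3)
  expect_lte(fit$sse, oracle$sse * (1 + 1e-6))
})

test_that("iterative fixed-period fitting agrees with the closed form", {
  withr::local_seed(7)
  for (i in 1:20) {
    prof <- random_profile()
    cf <- fit_cosinor(prof$t, prof$y)
    nl <- fit_cosinor_nls(prof$t, prof$y, period_mode = "fixed24")
    expect_lt(abs(nl$sse - cf$sse) / cf$sse, 1e-6)
    expect_lt(abs(clock_difference(nl$acrophase_clock, cf$acrophase_clock)), 1e-3)
  }
})

test_that("the bounded free-period fit recovers a noiseless 22.5-h rhythm", {
  grid <- circasal:::schedule_grid()
  y <- 10 + 5 * cos(2 * pi * (grid$elapsed_time - 2) / 22.5)
  fit <- fit_cosinor_nls(grid$elapsed_time, y, period_mode = "free_bounded")
  expect_equal(fit$period, 22.5, tolerance = 0.05)
  expect_equal(fit$mesor, 10, tolerance = 1e-3)
  expect_equal(fit$amplitude, 5, tolerance = 1e-3)
})

test_that("the free-period SSE never exceeds the fixed-period SSE", {
  withr::local_seed(11)
  for (i in 1:10) {
    prof <- random_profile()
    cf <- fit_cosinor(prof$t, prof$y)
    fr <- suppressWarnings(
      fit_cosinor_nls(prof$t, prof$y, period_mode = "free_bounded"))
    expect_lte(fr$sse, cf$sse + 1e-10)
    expect_gte(fr$period, 20)
    expect_lte(fr$period, 28)
  }
})

test_that("canonicalization resolves sign, form and modulus", {
  # negative cosine amplitude: peak shifts half a period
  r <- canonicalize_cosinor(10, -3, 10, form = "cosine")
  expect_equal(r$amplitude, 3)
  expect_equal(r$acrophase_clock, 22)
  # sine form peaks a quarter period after its phase parameter
  r <- canonicalize_cosinor(10, 5, 2, form = "sine")
  expect_equal(r$acrophase_clock, 8)
  # phases wrap into [0, 24)
  r <- canonicalize_cosinor(10, 5, 27, form = "cosine")
  expect_equal(r$acrophase_clock, 3)
})

test_that("a sine-form fit and a cosine-form fit give identical canonical output", {
  withr::local_seed(3)
  prof <- random_profile()
  a <- fit_cosinor(prof$t, prof$y, form = "cosine")
  b <- fit_cosinor(prof$t, prof$y, form = "sine")
  expect_equal(a$mesor, b$mesor)
  expect_equal(a$amplitude, b$amplitude)
  expect_equal(a$acrophase_clock, b$acrophase_clock)
})

test_that("predict_cosinor hits peak, trough and mesor crossings", {
  fit <- list(mesor = 10, amplitude = 5, acrophase_clock = 8, period = 24,
              clock_origin = 8)
  expect_equal(predict_cosinor(fit, 8), 15)
  expect_equal(predict_cosinor(fit, 20), 5)
  expect_equal(predict_cosinor(fit, 2), 10)
  # the fitted maximum equals mesor + amplitude at the acrophase
  withr::local_seed(5)
  prof <- random_profile()
  f <- fit_cosinor(prof$t, prof$y)
  expect_equal(predict_cosinor(f, f$acrophase_clock), f$mesor + f$amplitude)
})

test_that("fits are time-shift and scale equivariant", {
  withr::local_seed(19)
  for (i in 1:5) {
    prof <- random_profile()
    base <- fit_cosinor(prof$t, prof$y)
    delta <- runif(1, -30, 30)
    shifted <- fit_cosinor(prof$t + delta, prof$y)
    expect_lt(abs(clock_difference(shifted$acrophase_clock,
                                   (base$acrophase_clock + delta) %% 24)), 1e-9)
    expect_equal(shifted$mesor, base$mesor, tolerance = 1e-9)
    expect_equal(shifted$amplitude, base$amplitude, tolerance = 1e-9)
    expect_equal(shifted$r_squared, base$r_squared, tolerance = 1e-9)

    c_ <- runif(1, 0.1, 10)
    scaled <- fit_cosinor(prof$t, prof$y * c_)
    expect_equal(scaled$mesor, base$mesor * c_, tolerance = 1e-9)
    expect_equal(scaled$amplitude, base$amplitude * c_, tolerance = 1e-9)
    expect_equal(scaled$acrophase_clock, base$acrophase_clock, tolerance = 1e-6)
    expect_equal(scaled$r_squared, base$r_squared, tolerance = 1e-9)
  }
})

test_that("cosinor_fit_table fits every series and records both period modes", {
  cfg <- two_group_melatonin_config(seed = 21, missing_rate = 0)
  sim <- simulate_cohort(cfg)
  fits <- cosinor_fit_table(sim$samples)
  expect_equal(nrow(fits), 20)
  expect_true(all(fits$fit_ok))
  expect_true(all(fits$form == "cosine"))
  expect_true(all(fits$sse_free <= fits$sse + 1e-10))
  expect_true(all(fits$period_free >= 20 & fits$period_free <= 28))
})
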