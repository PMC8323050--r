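test_that("the exclusion rule drops series missing more than the threshold, per analyte", {
  vals_full <- cosinor_values(10, 5, 8)
  v5 <- vals_full; v5[1:5] <- NA
  v4 <- vals_full; v4[1:4] <- NA
  v6 <- vals_full; v6[1:6] <- NA
  samples <- dplyr::bind_rows(
    make_profile(v5, subject_id = "A", analyte = "cortisol"),
    make_profile(v4, subject_id = "B", analyte = "cortisol"),
    make_profile(vals_full, subject_id = "C", analyte = "cortisol"),
    make_profile(v6, subject_id = "C", analyte = "melatonin")
  )
  res <- apply_exclusion(samples, threshold = 4)
  key <- paste(res$excluded$subject_id, res$excluded$analyte)
  expect_setequal(key, c("A cortisol", "C melatonin"))
  retained <- dplyr::distinct(res$retained, subject_id, analyte)
  # 4 missing sits on the allowed side of the "more than four" boundary
  expect_true(any(retained$subject_id == "B"))
  # C stays for cortisol although its melatonin series is excluded
  expect_true(any(retained$subject_id == "C" & retained$analyte == "cortisol"))
  expect_match(res$excluded$reason[1], "missing data")

  # monotone: lowering the threshold never retains a previously excluded series
  for (th in 4:0) {
    ex_hi <- apply_exclusion(samples, threshold = th)$excluded
    ex_lo <- apply_exclusion(samples, threshold = max(th - 1, 0))$excluded
    expect_true(all(paste(ex_hi$subject_id, ex_hi$analyte) %in%
                      paste(ex_lo$subject_id, ex_lo$analyte)) || th == 0)
  }
})

test_that("students_t matches the pooled-variance formula and its symmetries", {
  withr::local_seed(83)
  a <- rnorm(12, 5, 2)
  b <- rnorm(10, 6, 2)
  r <- students_t(a, b)
  or <- pooled_t_oracle(a, b)
  expect_equal(r$t_statistic, or$t, tolerance = 1e-12)
  expect_equal(r$df, or$df)
  expect_equal(r$p_value, or$p, tolerance = 1e-12)

  sw <- students_t(b, a)
  expect_equal(sw$t_statistic, -r$t_statistic, tolerance = 1e-12)
  expect_equal(sw$p_value, r$p_value, tolerance = 1e-12)

  same <- students_t(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  w <- students_t(a, b, variant = "welch")
  ht <- t.test(a, b)
  expect_equal(w$t_statistic, unname(ht$statistic))
  expect_equal(w$df, unname(ht$parameter))

  expect_error(students_t(a, 5), "at least 2")
  expect_equal(students_t(rep(1, 3), rep(1, 4))$p_value, 1)
  expect_error(students_t(rep(1, 3), rep(2, 4)), "zero variance")
})

test_that("compare_all emits the full feature x analyte x pairing grid", {
  cfg <- default_cohort_config(seed = 89)
  sim <- simulate_cohort(cfg)
  res <- run_analysis(sim$samples)
  expect_equal(nrow(res$comparisons), 12 * 2 * 2)
  expect_true(all(res$comparisons$feature %in% feature_names()))
  expect_true(all(res$comparisons$significant[res$comparisons$computable] ==
                    (res$comparisons$p_value[res$comparisons$computable] < 0.05)))
})

test_that("groups too small for a test yield not-computable rows, no crash", {
  cfg <- default_cohort_config(seed = 97)
  sim <- simulate_cohort(cfg)
  fits <- cosinor_fit_table(sim$samples)
  ft <- feature_table(sim$samples, fits)
  # a single manic subject: comparisons against it are marked, not crashed
  solo <- ft[ft$group == "control", ][1, ]
  solo$group <- "mania"
  ft2 <- dplyr::bind_rows(ft, solo)
  comp <- compare_all(ft2, pairings = list(c("control", "mania")))
  expect_equal(nrow(comp), 24)
  expect_true(all(!comp$computable))
  expect_true(all(is.na(comp$p_value)))

  # a feature column entirely missing is likewise not computable
  ft3 <- ft
  ft3$period <- NA_real_
  comp3 <- compare_all(ft3, pairings = list(c("control", "depression")))
  expect_false(any(comp3$computable[comp3$feature == "period"]))
  expect_true(any(comp3$computable[comp3$feature == "avg_24h"]))
})

test_that("acrophase comparisons are invariant to the clock origin of the phases", {
  # the same phase pattern placed across midnight must give the same t test
  ftA <- tibble::tibble(
    subject_id = sprintf("S%d", 1:10),
    group = rep(c("control", "depression"), each = 5),
    analyte = "melatonin",
    period = 24, acrophase_clock = c(3.0, 3.4, 3.2, 2.9, 3.1,
                                     1.1, 1.4, 0.9, 1.2, 1.0),
    fitted_peak = 20, fitted_mesor = 10, avg_24h = 10, max_level = 20,
    range = 15, two_day_diff = 1,
    slope_day1 = -1, slope_day2 = -1, slope_night1 = 1, slope_night2 = 1,
    flags = ""
  )
  ftB <- ftA
  ftB$acrophase_clock <- (ftA$acrophase_clock - 2) %% 24  # straddles midnight
  rowA <- dplyr::filter(compare_all(ftA), feature == "acrophase_clock",
                        group_b == "depression")
  rowB <- dplyr::filter(compare_all(ftB), feature == "acrophase_clock",
                        group_b == "depression")
  expect_equal(rowA$t_statistic, rowB$t_statistic, tolerance = 1e-9)
  expect_equal(rowA$p_value, rowB$p_value, tolerance = 1e-9)
  expect_equal(clock_difference(rowA$mean_a, rowA$mean_b),
               clock_difference(rowB$mean_a, rowB$mean_b), tolerance = 1e-9)
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  cfg <- two_group_melatonin_config(seed = 101, missing_rate = 0)
  sim <- simulate_cohort(cfg)
  res <- run_analysis(sim$samples, p_adjust = "BH",
                      pairings = list(c("control", "depression")))
  expect_true("p_adjusted" %in% names(res$comparisons))
  ok <- res$comparisons$computable
  expect_true(all(res$comparisons$p_adjusted[ok] >= res$comparisons$p_value[ok]))
})

test_that("group summaries report mean, SEM and n per feature", {
  cfg <- two_group_melatonin_config(seed = 103, missing_rate = 0)
  sim <- simulate_cohort(cfg)
  ft <- feature_table(sim$samples, cosinor_fit_table(sim$samples))
  gs <- group_feature_summary(ft)
  row <- gs[gs$group == "control" & gs$feature == "avg_24h", ]
  expect_equal(row$n, 12)
  vals <- ft$avg_24h[ft$group == "control"]
  expect_equal(row$mean, mean(vals))
  expect_equal(row$sem, sd(vals) / sqrt(12))
})
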