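#' Apply the missing-data exclusion rule
#'
#' A subject x analyte series is excluded from statistical analysis when it
#' has missing measurements at more than `threshold` scheduled time points
#' (default 4 of the 14 canonical slots). Exclusion is decided per analyte:
#' a subject may be retained for cortisol yet excluded for melatonin.
#'
#' @param samples Samples tibble ([read_profiles()] dialect).
#' @param threshold Maximum tolerated number of missing slots; series with
#'   `n_missing > threshold` are excluded.
#' @return A list with `retained` (samples tibble restricted to retained
#'   series, schedule attribute preserved) and `excluded` (tibble of
#'   excluded series: keys, `n_missing`, `reason`).
#' @export
apply_exclusion <- function(samples, threshold = 4) {
  summ <- profile_summary(samples)
  excl <- summ[summ$n_missing > threshold, ]
  excl$reason <- sprintf("missing data at %d time points (> %d allowed)",
                         excl$n_missing, as.integer(threshold))
  drop_key <- paste(excl$subject_id, excl$analyte)
  keep <- !(paste(samples$subject_id, samples$analyte) %in% drop_key)
  retained <- samples[keep, ]
  attr(retained, "schedule") <- attr(samples, "schedule")
  list(retained = retained,
       excluded = excl[, c("subject_id", "group", "analyte", "n_missing", "reason")])
}

#' Two-sample Student's t test
#'
#' Two-sided two-sample t test, pooled-variance by default (the classical
#' Student test), Welch's unequal-variance form by option. Degenerate
#' inputs are resolved explicitly: zero pooled variance with equal means
#' gives `t = 0, p = 1`; zero variance with unequal means is an error.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 finite
#'   values.
#' @param variant `"pooled"` or `"welch"`.
#' @return A list with `t_statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`, `n_a`, `n_b`.
#' @export
students_t <- function(values_a, values_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a < 2 || n_b < 2) stop("each group needs at least 2 finite values")

  out <- list(mean_a = mean(values_a), mean_b = mean(values_b),
              sem_a = sd(values_a) / sqrt(n_a), sem_b = sd(values_b) / sqrt(n_b),
              n_a = n_a, n_b = n_b)
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (out$mean_a == out$mean_b) {
      df <- if (variant == "pooled") n_a + n_b - 2 else NA_real_
      return(c(list(t_statistic = 0, df = df, p_value = 1), out))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = (variant == "pooled"))
  c(list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value), out)
}

#' Compare every ledger feature between groups
#'
#' For each feature x analyte x group pairing, runs a two-sided Student's t
#' test on the per-subject feature values (missing values dropped listwise
#' within the comparison). The acrophase feature is additionally analyzed
#' circularly via [circular_comparison_table()]; this function reports the
#' linear t tests. Comparisons for which either group has fewer than 2
#' non-missing values are emitted with `computable = FALSE` rather than
#' dropped, so the output shape is always
#' `|features| x |analytes| x |pairings|`.
#'
#' @param features Feature table from [feature_table()] (retained subjects
#'   only).
#' @param pairings List of 2-character vectors `c(group_a, group_b)`.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @param p_adjust If `"BH"`, adds a Benjamini-Hochberg adjusted p-value
#'   column (`p_adjusted`, computed within analyte x pairing). The raw
#'   per-test p-values are always reported; with 12 features tested per
#'   hormone at raw alpha = .05 some false positives are expected, so the
#'   adjusted column is recommended for confirmatory use.
#' @return A tibble of comparison rows: `feature`, `analyte`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `t_statistic`, `df`, `p_value`, `significant` (p < .05), `computable`.
#' @export
compare_all <- function(features,
                        pairings = list(c("control", "depression"),
                                        c("control", "recovery")),
                        variant = c("pooled", "welch"),
                        p_adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  p_adjust <- match.arg(p_adjust)
  analytes <- sort(unique(features$analyte))
  n_out <- length(analytes) * length(pairings) * length(feature_names())
  col <- function(x) rep(x, n_out)
  out <- list(feature = col(NA_character_), analyte = col(NA_character_),
              group_a = col(NA_character_), group_b = col(NA_character_),
              n_a = col(NA_integer_), n_b = col(NA_integer_),
              mean_a = col(NA_real_), sem_a = col(NA_real_),
              mean_b = col(NA_real_), sem_b = col(NA_real_),
              t_statistic = col(NA_real_), df = col(NA_real_),
              p_value = col(NA_real_), significant = col(NA),
              computable = col(FALSE))
  i <- 0L
  for (analyte in analytes) {
    fa <- features[features$analyte == analyte, ]
    for (pair in pairings) {
      for (feat in feature_names()) {
        i <- i + 1L
        va <- fa[[feat]][fa$group == pair[1]]
        vb <- fa[[feat]][fa$group == pair[2]]
        va <- va[!is.na(va)]
        vb <- vb[!is.na(vb)]
        centre <- NULL
        if (feat == "acrophase_clock" && length(c(va, vb)) >= 1) {
          # a clock time is circular: centre on the pooled circular mean so
          # phases straddling midnight do not corrupt the linear test
          centre <- mean_vector(phase_angle(c(va, vb)))$mean_clock
          if (!is.na(centre)) {
            va <- clock_difference(va, centre)
            vb <- clock_difference(vb, centre)
          }
        }
        recentre <- function(m) {
          if (is.null(centre) || is.na(centre)) m else (centre + m) %% 24
        }
        out$feature[i] <- feat
        out$analyte[i] <- analyte
        out$group_a[i] <- pair[1]
        out$group_b[i] <- pair[2]
        out$n_a[i] <- length(va)
        out$n_b[i] <- length(vb)
        if (length(va)) out$mean_a[i] <- recentre(mean(va))
        if (length(va) > 1) out$sem_a[i] <- sd(va) / sqrt(length(va))
        if (length(vb)) out$mean_b[i] <- recentre(mean(vb))
        if (length(vb) > 1) out$sem_b[i] <- sd(vb) / sqrt(length(vb))
        res <- if (length(va) >= 2 && length(vb) >= 2) {
          tryCatch(students_t(va, vb, variant = variant),
                   error = function(e) NULL)
        }
        if (!is.null(res)) {
          out$t_statistic[i] <- res$t_statistic
          out$df[i] <- res$df
          out$p_value[i] <- res$p_value
          out$significant[i] <- res$p_value < 0.05
          out$computable[i] <- TRUE
        }
      }
    }
  }
  out <- tibble::as_tibble(out)
  if (p_adjust == "BH") {
    out <- out |>
      dplyr::group_by(.data$analyte, .data$group_a, .data$group_b) |>
      dplyr::mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}

#' Per-group feature summaries (mean, SEM, n)
#'
#' @param features Feature table from [feature_table()].
#' @return Long tibble: `analyte`, `group`, `feature`, `n`, `mean`, `sem`.
#' @export
group_feature_summary <- function(features) {
  features |>
    tidyr::pivot_longer(dplyr::all_of(feature_names()),
                        names_to = "feature", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$analyte, .data$group, .data$feature) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sem = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
}
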