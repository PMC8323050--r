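# circasal

Circadian rhythm analysis of two-day salivary cortisol and melatonin
profiles.

Studies of mood disorders commonly read the circadian clock non-invasively
from saliva: cortisol peaks shortly after waking (near 08:00 under a
controlled 22:00–06:00 sleep schedule) and melatonin peaks in the small
hours of the night. Comparing the timing, strength and day-to-day
stability of these rhythms between clinical groups — healthy controls
versus patients in a depressive or recovered state — requires a chain of
steps that is easy to get subtly wrong: a sampling timeline that crosses
midnight, cosinor curve fitting, a ledger of per-subject rhythm
parameters, circular statistics for phase, missing-data exclusion rules,
and group tests. `circasal` implements that chain as a tested, seeded,
reproducible pipeline for the standard design of seven clock-time samples
(08:00, 11:00, 14:00, 19:00, 22:00, 01:00, 05:00) on two consecutive days.

## The model

Each subject × hormone series is fitted with the single-component cosinor

    Y(t) = M + A · cos(2π (t − φ) / λ)

with mesor `M`, amplitude `A ≥ 0`, acrophase `φ` (clock time of the fitted
maximum) and wavelength `λ` fixed at 24 h for the primary fits (a bounded
free-period fit on [20, 28] h supplies the period feature). With `λ` fixed
the fit is an exact closed-form least-squares solution. Each series is then
condensed to twelve parameters (period, acrophase, fitted peak, mesor,
24-h average, anchored maximum, range, two-day difference, and four
daytime/night slopes), groups are compared feature-by-feature with
Student's t tests, and acrophases are additionally analyzed on the 24-h
circle: mean resultant vectors, the Rayleigh uniformity test and the
Watson–Williams F test for equality of mean directions.

Because raw data of this kind is rarely shared, the package includes a
synthetic cohort generator that emulates the sampling design (cosinor
truths per subject, multiplicative assay-CV noise, sporadic missingness,
group effects such as a melatonin phase advance in depression), so the
entire pipeline is verifiable by parameter-recovery simulation.

## Worked example

```r
library(circasal)

cfg <- default_cohort_config(seed = 42)   # study-default cohort
sim <- simulate_cohort(cfg, dir = "sim")  # writes profiles.csv + truth.csv
res <- run_analysis(sim$samples)

subset(res$circular, analyte == "melatonin" & group_b == "depression")
#>   analyte   group_a group_b   n_a   n_b mean_clock_a mean_clock_b ... F_statistic  p_value
#> 1 melatonin control depression 12     8         3.62         1.33          17.0    0.000631

subset(res$comparisons, feature == "acrophase_clock" & analyte == "melatonin" &
       group_b == "depression")[, c("mean_a", "mean_b", "t_statistic", "p_value")]
#>   mean_a mean_b t_statistic  p_value
#> 1   3.65   1.33        4.15 0.000607
```

The simulated control melatonin rhythm peaks at a mean clock time of about
03:37 and the depression group at about 01:20 — the generator's built-in
~2.3-h phase advance — and both the circular Watson–Williams test and the
(circularly centred) Student's t test on acrophase detect it at these
group sizes (12 vs 8). `res$features` holds the twelve-parameter ledger
per subject, `res$comparisons` all 48 feature × analyte × pairing tests,
and `res$exclusions` any series dropped by the missing-data rule (more
than 4 of 14 slots missing).

File-based equivalents are available for scripting
(`cmd_simulate()`, `cmd_analyze()`, `cmd_report()`, or
`inst/scripts/circasal.R` for a shell entry point), and
`read_profiles()`/`write_profiles()` define the long-format CSV dialect
for real data (subject_id, group, analyte, day, clock_time, value).

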