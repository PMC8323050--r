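---
title: "Assessing circadian rhythmicity in two-day salivary hormone profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing circadian rhythmicity in two-day salivary hormone profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(circasal)
```

# The problem

Salivary cortisol and melatonin are the standard non-invasive readouts of
the human circadian system: cortisol surges around waking (a morning peak
near 08:00 under a 22:00–06:00 sleep schedule) and melatonin rises after
dim-light onset to a nocturnal maximum in the small hours. Mood-disorder
research compares the *timing* (phase), *strength* (amplitude) and
*day-to-day stability* of these rhythms between clinical groups — for
example healthy controls versus patients in a depressive episode, where a
phase advance of melatonin and a damped cortisol morning maximum are the
signals of interest.

`circasal` implements a complete, testable version of this analysis for a
fixed sampling design: saliva collected at seven clock times (08:00, 11:00,
14:00, 19:00, 22:00, 01:00, 05:00) on two consecutive days, giving up to 14
measurements per subject and hormone. Because raw clinical data of this
kind is rarely deposited, the package pairs the analysis pipeline with a
synthetic cohort generator that emulates the design, so that every stage
can be verified end-to-end by parameter-recovery simulation.

# Timeline convention

The two night samples cross midnight: the "day-1" 01:00 and 05:00
collections happen in the small hours of calendar day 2. All computation
therefore runs on a **continuous elapsed-time axis** anchored at the first
scheduled sample (day-1 08:00 = 0 h), on which the canonical slots fall at
0, 3, 6, 11, 14, 17, 21 h and those values + 24. Clock time is recovered as
`(8 + elapsed) mod 24`. Two consequences worth stating prominently:

* slopes and cosinor fits are always computed against elapsed hours, never
  against raw clock numerals — otherwise the 01:00 sample would sort after
  08:00 and invert the night axis;
* whether a night sample is labelled with the sampling day or the calendar
  day is a design convention. We assign it to the *sampling* day it closes,
  which is the reading consistent with a protocol described as two
  consecutive sampling days; `elapsed_time()` and `elapsed_to_slot()` make
  the convention explicit and invertible.

Missing measurements are encoded as absent values (`NA`), never sentinel
zeros: downstream means and slopes must skip them, not absorb them.

# The cosinor model

Each subject × hormone series is fitted with the standard single-component
cosinor
$$ Y(t) = M + A \cos\!\big( 2\pi (t - \phi) / \lambda \big), $$
with mesor $M$, amplitude $A \ge 0$, acrophase $\phi$ (reported as the
clock time of the fitted maximum, in $[0, 24)$) and wavelength $\lambda$
fixed at 24 h for all primary fits. Two parameterization conventions
circulate in this literature — a cosine form for melatonin and a sine form
for cortisol. They are exact reparameterizations of one another (a sine
curve peaks a quarter period after its phase parameter), so the package
treats `form` as a recorded convention, canonicalizes every fit to
(non-negative amplitude, peak clock time), and the two hormones become
directly comparable.

**Estimation.** With $\lambda$ fixed, the model is linear in $M$ and in the
rectangular coefficients $a, b$ of $a\cos\omega t + b\sin\omega t$:
`fit_cosinor()` solves ordinary least squares in closed form and converts
$A = \sqrt{a^2 + b^2}$, $\phi = \operatorname{atan2}(b, a)/\omega$. This is
the exact global optimum — no iteration, no starting-value sensitivity.
`fit_cosinor_nls()` additionally offers the conventional iterative
refinement (Levenberg–Marquardt in $(M, A, \phi)$, started at the closed
form; it can only confirm the optimum) and a **bounded free-period mode**:
the period is profiled over $[20, 28]$ h — for each candidate period the
conditional optimum is the closed form, and the profiled sum of squares is
minimized by a 0.25-h grid scan plus golden-section refinement. Profiling
is robust where a joint 4-parameter iteration can stall, and it guarantees
the free-period SSE never exceeds the fixed-period SSE.

A note on the period: the primary fits fix $\lambda = 24$ h, yet a fitted
"period" is also a reported feature. These coexist deliberately: acrophase
and all other curve features come from the fixed-24 fit (entrained
subjects have a 24-h observed period by definition), while the period
feature alone comes from the free fit and measures *apparent* period —
with only two sampled cycles it reflects phase drift and noise rather than
true oscillator period, which is why it is bounded and kept separate. The
bounds are configurable (`period_bounds`).

**Degenerate fits.** A series with amplitude below $10^{-8} \cdot |M|$ is
flagged degenerate: amplitude is reported as 0 and the acrophase as
undefined (`NA`), and such series are excluded from all circular phase
analysis rather than assigned an arbitrary phase. A constant series also
has an undefined $R^2$ (zero total sum of squares).

**Group-level curves.** Figures of group profiles fit the cosinor to the
pointwise group-mean profile (`plot_group_profile()`), which is the
display convention in this literature; all statistics use per-subject fits
because the group tests need per-subject values.

# The twelve-parameter ledger

`extract_features()` condenses each series to twelve parameters, in a fixed
panel order (see `?extract_features` for the full definitions): the free
period; the acrophase, fitted peak ($M + A$) and mesor from the fixed fit;
the plain mean of all present measurements (`avg_24h`); the **anchored
maximum** `max_level` — the measurement at day-2 08:00 for cortisol and
day-2 05:00 for melatonin; the empirical `range`; the `two_day_diff`
replicability statistic; and four linear slopes (daytime and night, each
day).

Choices that were genuinely open:

* **Anchored versus empirical maximum.** `max_level` is the value at the
  analyte's anchor slot, not the per-subject empirical maximum; the
  empirical extreme is used only inside `range`. The two "maxima" measure
  different things (a fixed-time morning/night level versus overall spread)
  and are kept distinct.
* **Two-day difference.** Defined as the *mean* absolute difference over
  clock times present on both days (a sum variant is available via
  `two_day_stat = "sum"`). The mean is robust to missingness: a subject
  with fewer matched pairs is not mechanically rewarded with a smaller
  statistic.
* **`avg_24h`** is the plain mean of all present samples; no reweighting of
  the twice-daily 08:00 slot is attempted.
* **Night slopes.** Cortisol's night slope climbs into the morning peak,
  so its triplet is 01:00, 05:00 and the *following* 08:00 — elapsed 17,
  21, 24 for night 1. Melatonin's night rise is 22:00, 01:00, 05:00 —
  elapsed 14, 17, 21. Night 2 shifts each triplet by +24 h; for cortisol
  this ends at a third-morning 08:00 that the two-day design never
  samples, so cortisol's `slope_night2` is a two-point slope under the
  canonical schedule and carries a `slope_night2_2pt` flag. Any slope
  triplet with fewer than two present points is missing; with exactly two
  it is the two-point slope, flagged as degraded.

# Circular phase statistics

Acrophases live on a 24-h circle; `phase_angle()` maps clock hours to
radians with midnight at angle 0. Group phase is summarized by the mean
resultant vector (`mean_vector()`): direction = mean peak time, length
$R \in [0, 1]$ = phase agreement. The Rayleigh test ($z = nR^2$) checks
angular uniformity, and group differences in mean direction use the
Watson–Williams $F$ test with the standard concentration correction
$K = 1 + 3/(8\hat\kappa)$, $\hat\kappa$ estimated from the mean resultant
length by the usual three-regime approximation (regime boundaries at
$\bar R = 0.53$ and $0.85$). The test assumes reasonably concentrated von
Mises samples; results carry an `assumption_warning` when
$\hat\kappa < 2$. Per-subject fit strength ($R^2$) can weight the *display*
vectors, but the Watson–Williams test always uses unweighted angles, as its
theory requires.

Because acrophase is circular, the linear Student's t test applied to it
(the conventional companion analysis) is computed on phases **centred on
the pooled circular mean** of the two groups being compared: each value
enters as its signed shortest distance from that centre. For groups that
sit well away from midnight this is numerically identical to the naive
test; for phases straddling midnight it prevents a 23.8-versus-0.2
artifact. Both routes — linear t and Watson–Williams — are always reported
side by side, since they formalize "same timing" differently and need not
agree near $p = .05$.

# Group comparison

The **exclusion rule** drops a subject × analyte series with missing data
at more than four of the fourteen scheduled time points (threshold
configurable). Exclusion is per analyte: a subject can be retained for
cortisol and excluded for melatonin. `compare_all()` then runs a two-sided
pooled-variance Student's t test for every feature × analyte × pairing
(default pairings: control–depression and control–recovery); Welch's form
is available by option. Groups with fewer than two usable values (e.g. a
single manic patient) yield rows marked not computable rather than errors,
so the output grid always has $12 \times |\text{analytes}| \times
|\text{pairings}|$ rows.

No multiple-testing correction is applied by default — twelve features per
hormone are each tested at raw $\alpha = .05$, so about one false positive
per hormone is expected under the null; a Benjamini–Hochberg column is
available (`p_adjust = "BH"`) and recommended for confirmatory claims.

# The synthetic cohort generator

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, not a physiological secretion model. Per subject, truth
cosinor parameters are drawn from group-level distributions: mesor and
amplitude from normals truncated at 0 (amplitude further truncated at the
mesor, since a concentration curve must stay non-negative), acrophase from
a wrapped normal on the clock, period fixed at 24 h by default (entrained
subjects; apparent period variation in fits then arises from noise, as it
does in practice). Observations are the truth curve times multiplicative
Gaussian noise $1 + \varepsilon$, $\varepsilon \sim N(0, \text{CV})$,
truncated at 0, with each slot independently missing at a configurable
rate. Multiplicative noise matches how immunoassay imprecision is reported
(a coefficient of variation, i.e. proportional to level) across hormone
levels spanning an order of magnitude within a day.

Defaults (`default_cohort_config()`) encode the study conditions the
pipeline is meant to analyze: group sizes 12/10/4 (cortisol) and 12/8/3
(melatonin) for control/depression/recovery; control cortisol peaking at
08:00 with mesor ≈ 4 ng/ml and amplitude ≈ 3.5 ng/ml; control melatonin
peaking around 03:50 with mesor ≈ 12 pg/ml and amplitude ≈ 10 pg/ml; the
depression group with a damped cortisol amplitude (≈ 2.2 ng/ml) and a
melatonin acrophase around 01:30 — a ≈ 2.3-h phase advance; the recovery
group duplicating the control distributions (recovered patients resemble
controls). Noise CVs default to the intra-assay imprecision of the
respective assays, 6.1% (cortisol) and 10.8% (melatonin); missingness to a
sporadic 5% per slot; between-subject circular SD of acrophase to 1 h,
which produces tight control phase clusters (resultant length ≈ 0.97).
Group mean levels and spreads are order-of-magnitude choices in the
hormones' physiological ranges — published figures report them only
graphically — and must not be read as estimates of any particular study's
values.

What the generator deliberately does **not** emulate: pulsatile secretion,
the cortisol awakening response's fine structure, non-sinusoidal melatonin
waveforms (real melatonin is near zero all day and rises sharply at
night), assay floor effects and inter-assay drift, or informative
missingness (slots are dropped at random). Passing recovery tests
therefore show that the *pipeline* is correct under its own model; they do
not certify behaviour on waveform shapes the cosinor only approximates.

`make_null_config()` collapses all groups onto one shared truth
distribution, which is how the package checks that each feature's t test
and the Watson–Williams test hold their nominal type-I error.

# Numerical choices and problem sizes

All randomness flows from explicit integer seeds (one per configuration);
reruns are byte-identical. Tolerances: closed-form versus iterative fits
agree to $10^{-6}$ relative SSE; degenerate amplitude threshold
$10^{-8}\,|M|$; the free-period profile uses a 0.25-h grid with
golden-section refinement to $10^{-8}$. The test suite sizes its
simulations to what the properties need: 200 random profiles for the
fit-equivalence check, 500 subjects for noisy acrophase recovery
(median absolute error < 0.5 h), 100 replicate cohorts for phase-advance
detection at the default group sizes, and 1,000 replicate null cohorts for
the type-I calibration (empirical rejection within [3.5%, 6.5%] at
$\alpha = .05$).

# Limitations

* The pooled t test is exactly calibrated only for near-normal features.
  Features dominated by per-subject estimation noise — above all the free
  period, which under the entrained-subject default has no between-subject
  truth variance — have scale-mixture distributions (each subject's fit
  precision depends on their amplitude-to-noise ratio) and test slightly
  conservatively: in the package's own null calibration at the melatonin
  group sizes, the period feature rejects at about 3% rather than 5%,
  while phase, level and slope features sit near nominal.
* The cosinor is a one-harmonic model; melatonin's flat-day/sharp-night
  waveform is only approximated, and fitted mesor/amplitude for such
  shapes are waveform-dependent summaries, not secretion parameters.
* Two days of seven samples cannot estimate true endogenous period; the
  free-period feature is an apparent period, bounded to [20, 28] h.
* The t tests are unadjusted across twelve features by default, mirroring
  the analysis convention in this literature; use the BH option for
  confirmatory work.
* No hierarchical/second-order circular analysis (e.g. confidence cones
  for mean direction) is provided.

# A minimal run

```{r, eval = FALSE}
cfg <- default_cohort_config(seed = 1)
sim <- simulate_cohort(cfg, dir = "sim")
res <- run_analysis(sim$samples)
dplyr::filter(res$comparisons, feature == "acrophase_clock",
              analyte == "melatonin")
dplyr::filter(res$circular, analyte == "melatonin")
```
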