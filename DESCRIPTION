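Package: circasal
Title: Circadian Rhythm Analysis of Two-Day Salivary Hormone Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing circadian rhythmicity in two-day salivary
    cortisol and melatonin profiles sampled on a fixed clock-time schedule.
    Implements fixed-24-hour and bounded free-period cosinor fitting with a
    closed-form least-squares solution, extraction of a twelve-parameter
    rhythm ledger (acrophase, fitted peak and mesor, average level, anchored
    maximum, range, two-day replicability, and daytime/night slopes),
    circular phase statistics (mean resultant vectors, Rayleigh test,
    Watson-Williams F test), group comparison with a missing-data exclusion
    rule, and a seeded synthetic cohort generator emulating the sampling
    design so every stage can be verified by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
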