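Package: mbsced
Title: Multiple-Baseline Single-Case Analysis of Sedentary Behavior from
    Posture-Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for randomized multiple-baseline (single-case experimental
    design) studies of movement behavior measured with thigh-worn posture
    monitors. Reads ActivPAL-style event streams and wake/sleep diaries,
    derives daily movement-behavior metrics (total sedentary time, the
    fragmentation index, prolonged-bout accumulation, light and
    moderate-to-vigorous physical activity), screens participants against a
    sedentary-pattern eligibility rule, runs the Wampold-Worsham
    randomization test over staggered baseline durations (exact enumeration
    or Monte Carlo), computes percentage-exceeding-the-median (PEM) effect
    sizes with category labels and phase summaries, and produces
    visual-analysis artifacts with baseline mean and 2-SD bands. A synthetic
    cohort generator emulates the day-to-day statistical structure of highly
    sedentary stroke survivors so that every stage is testable without
    access to raw accelerometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
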