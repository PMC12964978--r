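Package: pneumocea
Title: Matched-Cohort Effectiveness and Cost-Effectiveness Analysis for
    Spontaneous Pneumothorax Treatment Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline comparing video-assisted thoracoscopic
    surgery (VATS) against chest tube drainage for first-episode primary
    spontaneous pneumothorax with blebs: propensity-score caliper matching
    with standardized-mean-difference balance diagnostics, recurrence and
    time-to-event effect measures (Kaplan-Meier, log-rank, Cox), a
    utility-based QALY decision model with continuous discounting and
    incremental cost-effectiveness ratios, deterministic one-way scenario
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    plane and acceptability-curve outputs. Includes a calibrated synthetic
    cohort generator so the full pipeline is testable without patient-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
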