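Package: gestwear
Title: Activity and Gesture Digital Outcome Measures from Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive digital outcome measures for negative symptoms
    from wrist-worn tri-axial accelerometry sampled at 20 Hz. Implements
    human-activity-recognition windowing and a baseline classifier separating
    ambulatory from stationary activity with a subject-wise train/validation/
    test protocol, rule-based gesture-event detection from the 1-s moving
    standard deviation of the acceleration magnitude with a 0.01 g threshold
    and sub-second gap merging, per-event gesture power, per-patient feature
    aggregation (activity-time ratio, median daily gesture count, gesture
    power, monitoring ratio), effort-choice task scoring, and a Spearman
    correlation stage linking sensor features to clinical scores. Includes a
    seeded synthetic-cohort generator (signal-level recordings and day-level
    cohorts with Gaussian-copula coupling to clinical scores) so the whole
    pipeline is testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
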