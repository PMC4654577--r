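Package: triadstress
Title: Real-Time Stress, Speaking Turns, and Emergent Status in Conversing Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of status emergence in small
    conversational groups instrumented with thumb photoplethysmography (PPG)
    and salivary endocrine panels. Extracts per-beat pulse rate and
    peak-to-peak blood-volume amplitude from PPG traces with annotation-driven
    artifact excision and step-gain correction, builds speaking turns from
    utterance tracks, derives speaking/listening normalization ratios,
    aggregates seven status components into triad ranks with a
    consistent-differentiation tie rule, and fits diagonal-covariance
    multilevel models (with Satterthwaite degrees of freedom, mean-centered
    interactions, and simple-slope decomposition) relating testosterone,
    cortisol, and alpha-amylase to emergent rank. Includes a calibrated
    synthetic-session generator so every stage has a ground-truth
    parameter-recovery test, and post-hoc power for joint F-tests via the
    noncentral F distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
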