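Package: pesbias
Title: Unbiased Post-Error Slowing Estimation for Interference Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of post-error slowing (PES) from trial-level
    behavioral logs of interference tasks such as the Eriksen flanker
    task. Provides sequence-aware trial classification (post-correct,
    pre-error, post-error, with exclusion of ambiguous single correct
    trials between two errors), reaction-time filtering including
    median-absolute-deviation outlier rejection, four PES estimators
    (traditional and robust baselines, each uncorrected or corrected
    for congruency imbalance) in mean- and median-based forms,
    congruency-imbalance diagnostics stratified by response-stimulus
    interval, an analytic mean-bias formula and a numerical
    mixture-of-normals median-bias model, multilevel bootstrap
    confidence intervals, and a seeded synthetic flanker-task
    generator with conflict adaptation and slow performance drifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
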