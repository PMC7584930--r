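Package: sifi
Title: Survival-Inferred Fragility Index for Two-Arm Time-to-Event Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the survival-inferred fragility index (SIFI), a
    time-aware robustness measure for two-arm survival comparisons obtained
    by iteratively reassigning (or cloning) extreme survivors between arms
    until a two-sided log-rank test crosses the significance threshold.
    Includes the four SIFI variants (flip/clone of best/worst survivors), a
    comparator fragility measure based on appending artificial
    average-exposure patients, a Weibull accelerated-failure-time trial
    simulator with a factorial grid runner, reconstruction of individual
    patient data from digitized Kaplan-Meier curves and number-at-risk
    tables, and aggregate summaries over tables of published trials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
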