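Package: afburden
Title: Atrial Fibrillation Burden Trends and Near-Term Hospitalization Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily diagnostics from insertable cardiac
    monitors (ICMs) with a change-from-baseline approach to atrial
    fibrillation (AF) burden. Implements cumulative and simple moving
    averages of daily device parameters, crossover trend states (sinus,
    below-average, above-average, and above-average burden with declining
    activity), prespecified duration and quantity burden thresholds, rule
    mining from bootstrapped classification trees with matching against
    clinical comparators, and holdout validation via incidence-rate ratios,
    day-level AUROC, event-yield, and Poisson rate comparison. Includes a
    synthetic cohort generator with hazard-linked cardiovascular
    hospitalization events for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
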