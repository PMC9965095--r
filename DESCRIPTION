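Package: frailscreen
Title: Frailty Phenotype Scoring and Gender-Stratified Screening Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the modified Fried physical-frailty phenotype
    (exhaustion, weak grip strength, slow walking time, unintentional weight
    loss, low physical activity) from raw survey measures, classifies
    participants as frail at a configurable deficit threshold, and evaluates
    every single and dual component as a screening marker against the
    composite phenotype: 2x2 contingency tables, sensitivity, specificity,
    predictive values and prevalence with Wilson continuity-corrected
    confidence intervals, survey-weighted descriptive tables and chi-square
    tests. Includes a seeded synthetic cohort generator with a latent-liability
    dependence structure emulating a large ageing survey, so the whole
    pipeline is reproducible without restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
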