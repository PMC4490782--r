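Package: claimsignal
Title: Directed Adverse Drug Reaction Signal Detection from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for directed discovery of possible adverse drug
    reactions from administrative claims data. Reconstructs incident drug
    courses from pharmacy dispensings, detects outcome episodes of care from
    primary diagnoses, builds per-outcome propensity-score and Mahalanobis
    matched new-user cohorts, and estimates incidence densities,
    pair-stratified recurrent-event Cox hazard ratios, and case-crossover
    odds ratios. Includes a synthetic-claims simulator with explicit
    confounding-by-indication structure so every stage of the pipeline can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
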