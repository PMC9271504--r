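Package: sharedcare
Title: Safety Monitoring and Survivorship Analytics for Shared-Care Cancer Follow-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating shared-care follow-up programs for cancer
    survivors. Implements a truncated fully sequential stopping rule for
    failures in relapse detection (Wald-type boundaries with simulation
    calibration, operating characteristics and sample-size search),
    visit-level failure adjudication for follow-up ledgers, the SCORE
    10-year cardiovascular risk model with a survivor age adjustment and
    NCEP-ATP III metabolic-syndrome classification, HADS-A and RAND-36
    questionnaire scoring, and a synthetic cohort generator that emulates
    the visit schedule, incident rates and measurement distributions of a
    shared-care testicular-cancer survivorship program.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
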