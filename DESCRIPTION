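Package: ckdvalid
Title: Validating Administrative-Data Case-Finding Algorithms for Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating claims-based (administrative-data)
    case-finding algorithms for chronic kidney disease (CKD) against a
    laboratory working standard built from repeated serum creatinine
    measurements. Implements the 2021 race-free CKD-EPI creatinine
    equation and eGFR staging, longitudinal working-standard labelling
    with a configurable chronicity gap, a rule-based classifier over
    linked health-information-system events (hospital discharges, co-pay
    exemptions, outpatient specialist services, drug dispensings),
    stratified diagnostic-accuracy statistics (sensitivity, specificity,
    predictive values, prevalence with Wald or Wilson confidence
    intervals), and a synthetic linked-records generator with known
    ground truth for end-to-end testing and power studies.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
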