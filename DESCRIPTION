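Package: triagecc
Title: Diagnostic Accuracy of Prehospital Major Trauma Triage Under a
    Case-Cohort Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates prehospital injury cohorts with the statistical
    structure of an English regional trauma-network population, applies
    case-cohort sampling with deterministic record linkage, evaluates
    declarative step-wise major-trauma triage tools against incident
    records, classifies records against consensus and Injury Severity
    Score based reference standards, and estimates diagnostic accuracy
    (sensitivity, specificity, likelihood ratios, post-test
    probabilities) overall, by ambulance service, by age group, and by
    cumulative triage-tool step.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
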