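Package: cinvaudit
Title: Antiemetic Guideline Concordance Auditing for Pediatric and AYA
    Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Audits prophylactic antiemetic prescribing against the ASCO
    2006 and 2017 antiemetic guidelines in administrative-claims-style
    inpatient chemotherapy records for patients under 30 years of age.
    Provides a synthetic cohort generator emulating Japanese DPC-like
    event tables, emetogenic risk classification of chemotherapy
    administrations including dose-per-body-surface-area rules for
    cyclophosphamide and cytarabine, declarative guideline rule sets with
    overuse/underuse decomposition of discordant regimens, stratified
    regimen frequency tables with binomial confidence intervals, and
    logistic regression of concordance on patient factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
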