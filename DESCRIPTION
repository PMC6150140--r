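Package: naraudit
Title: Audit and Feedback Analytics for Newborn Admission Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the completeness and prescribing quality of
    standardised newborn admission records (NARs) in routine hospital care.
    Provides a versioned data dictionary for the six-domain, 50-variable NAR
    used in Kenyan newborn units; binary documentation-completeness scoring
    aggregated by domain and six-month period with Wilson binomial confidence
    intervals; variable-level missingness stratification; a weight-banded
    gentamicin dosing-correctness classifier (3 mg/kg below 2 kg, 5 mg/kg at
    or above 2 kg, once daily, within a 20 percent margin); and a seeded
    synthetic cohort generator that emulates the statistical structure of a
    high-volume neonatal unit for end-to-end testing of the audit pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
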