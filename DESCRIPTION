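Package: checounts
Title: Subnational Health Expenditure Accounting Under SHA 2011
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Top-down estimation of Current Health Expenditure (CHE) for a
    subnational population under the System of Health Accounts 2011 (SHA 2011).
    Estimates allocation coefficients from institution-level survey microdata,
    scales provincial financial aggregates into an accounts cube indexed by
    provider type, health-care function, financing scheme, ICD-10 disease
    chapter and single-year age bin, and restricts the cube to a target
    subpopulation (children aged 0-14). Includes a synthetic-data generator
    that emulates a multistage institution survey with known ground truth,
    readers and writers for the encounter/finance/aggregate record families,
    ICD-10 chapter and GBD broad-cause classification tables, and renderers
    for the provider, disease-by-age and financing report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
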