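Package: dialclaims
Title: Claims-Based Case Definitions for Chronic Dialysis and Their
    Validation Against a Registry Reference Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements four temporal case definitions that identify chronic
    dialysis patients from outpatient physician billing claims (one claim; two
    claims; two claims at least 90 days apart; continuous claims spanning 90
    days with no gap greater than 21 days), the index-date rule for cohort
    entry, and the agreement-validation framework used to compare a claims
    definition against an end-stage renal disease registry reference standard
    (sensitivity, positive predictive value, Cicchetti-Feinstein positive
    agreement, Cohen's kappa with Landis-Koch categories). A seeded synthetic
    claims/registry generator emulates chronic dialysis billing streams,
    temporary dialysis for acute kidney injury, missed billings, and early
    death, so every stage runs without access to real administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
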