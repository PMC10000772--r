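Package: artclaims
Title: Drug Utilization, Adherence and Cost Analysis for Antiretroviral
    Therapy in Administrative Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds treatment cohorts of HIV patients on antiretroviral
    therapy (ART), in particular tenofovir alafenamide (TAF) based regimens,
    from linked administrative claims tables (demographics, pharmacy
    dispensations, hospital discharges, outpatient services). Computes
    proportion-of-days-covered (PDC) adherence from dispensation coverage
    timelines with carry-forward stockpiling, classifies persistence, switch
    and discontinuation from last-quarter dispensing, scores baseline
    comorbidity with a Charlson index modified to exclude the HIV item,
    aggregates annualized healthcare resource use and direct costs by cost
    item with mean + 3 SD outlier trimming, and fits a gamma generalized
    linear model with identity link to non-ART costs. Ships a synthetic
    claims generator so the full pipeline runs end to end with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
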