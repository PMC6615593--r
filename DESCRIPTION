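Package: denomqc
Title: Quality and Consistency Flags for Immunization Programme Denominators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the quality of the target-population denominators
    that national immunization programmes report annually (live births for
    birth-dose vaccines such as BCG, surviving infants for infant vaccines such
    as DTP3). Builds the country-by-year reporting grid, applies an auditable
    inclusion/exclusion cascade, computes administrative coverage, year-to-year
    percent differences, percent differences against reference population
    projections and the implied infant mortality rate, and evaluates nine
    accuracy and consistency flags per country-year. Includes tabulation of
    flag tallies, flag-count distributions, regional denominator sums and
    direction-of-difference counts, plus a seeded synthetic panel generator
    with planted anomalies and a truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
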