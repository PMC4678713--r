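Package: heatburden
Title: Health and Climate Impacts of City Building-Stock Heating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic, scalable city-level model chaining building-stock
    dynamics (cohorts, new construction, age-gated renovation), heating-energy
    demand, fuel use and emissions (fossil and total CO2, PM2.5),
    intake-fraction based population exposure, and attributable premature
    mortality expressed as disability-adjusted life years (DALY). Policies are
    declared outside the core model and expanded automatically into scenario
    indices; uncertain inputs are propagated by Monte Carlo through
    index-aligned table arithmetic; input importance is ranked by absolute
    Spearman correlation with a monetized combined climate and health outcome.
    Ships synthetic city generators emulating a district-heat dominated Nordic
    city and a Central European city for fully reproducible offline runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
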