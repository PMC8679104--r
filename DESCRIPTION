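Package: hygienecost
Title: Costing Universal Household Hand Hygiene in Least Developed Countries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A societal-perspective costing model for achieving universal basic
    hand hygiene in household settings across least developed countries over a
    ten-year scale-up. Combines country-level quantities (households without a
    handwashing facility, from JMP-style coverage estimates, household sizes and
    population projections) with prices of promotion campaigns, handwashing
    facilities, soap and water, standardised across currencies and years via GDP
    deflators and purchasing-power parity. Supports capital/recurrent cost
    cycles with useful lives, discounting, gamma-prior Monte Carlo uncertainty
    analysis with percentile intervals, deterministic one-way (tornado)
    sensitivity scenarios including economies of scale, and a synthetic-data
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
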