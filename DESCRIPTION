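Package: cariesim
Title: Microsimulation of Childhood Dental Caries and Dental Workforce
    Expansion in Shortage Areas
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-level decision-analytic microsimulation of dental
    caries among US children, with a focus on dental Health Professional
    Shortage Areas (HPSAs).  Generates seeded synthetic populations over a
    joint demographic structure, simulates annual caries incidence,
    treatment, and complications (abscess, tooth loss), converts National
    Health Service Corps (NHSC) budget scenarios into dentist
    full-time-equivalents and their utilization and caries-risk effects,
    accrues discounted costs and quality-adjusted life years, calibrates
    incidence to prevalence targets, and quantifies uncertainty through
    one-way (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
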