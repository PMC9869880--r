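Package: elemrisk
Title: Health Risk Assessment of Elemental Impurities in Oral Supplements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for elemental-impurity health risk assessment
    of orally administered supplements quantified by ICP-MS. Converts
    instrument readings to matrix concentrations through calibration curves,
    limit-of-detection censoring and the sample dilution chain; computes the
    deterministic risk metrics used in regulatory screening (estimated daily
    intake, hazard quotient, hazard index, lifetime cancer risk, permitted
    daily exposure screening against ICH Q3D / USP <232> limits); and
    propagates uncertainty in intake rate, body weight and concentration
    through a seeded Monte Carlo simulation with percentile-based decisions.
    Ships the regulatory constants (oral reference doses, permitted daily
    exposures, cancer slope factors, detection limits and calibration
    parameters) for the ten elements routinely screened in oral products,
    plus a synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
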