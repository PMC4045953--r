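Package: rxcohort
Title: New-User Cohorts, Incidence Trends and Synthetic Registries for
    Prescription Dispensing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacoepidemiological analysis of longitudinal
    prescription dispensing registries, built around the new-user design
    for blood glucose-lowering drugs (ATC group A10). Classifies prevalent
    and incident drug users with configurable washout and lookforward
    windows, distinguishes insulins-only users as a proxy for Type 1
    diabetes, estimates person-year incidence rates and prevalence
    proportions with confidence intervals, fits Poisson log-linear trend
    models (incidence rate ratios per calendar year, likelihood-ratio
    tests) via an internal IRLS solver, and ships a synthetic
    dispensing-registry simulator with known ground truth covering onset
    hazards with calendar trends, treatment-modality mixes including
    OAD-to-insulin switching, gestational diabetes, off-label metformin
    use, and registry truncation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
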