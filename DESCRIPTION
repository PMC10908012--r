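Package: tcscea
Title: Cost-Utility Analysis of Transitional Care for Older COPD Inpatients
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A six-state Markov cohort model comparing transitional care
    services with usual care for older inpatients with chronic obstructive
    pulmonary disease. Implements the full cost-utility pipeline: validated
    parameter tables (transition proportions, relative risks, per-state
    costs, utilities, additional mortality ratios), a synthetic
    Gompertz-Makeham life table and claims-like outcome generator, quarterly
    cohort traces with half-cycle correction and discounting, incremental
    cost-utility ratios with dominance classification, one-way deterministic
    sensitivity analysis with tornado ordering, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
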