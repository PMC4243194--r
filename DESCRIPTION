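Package: crtpair
Title: Pair-Matched Cluster Randomized Trial Analysis for Binary Survey Outcomes
Version: 0.1.0
Authors@R:
    person("crtpair", "maintainers", email = "crtpair@example.org", role = c("aut", "cre"))
Description: Two-stage cluster-level analysis of pair-matched cluster
    randomized trials with binary outcomes built from survey items:
    composite outcome construction from item-level responses, crude
    weighted analysis-of-variance risk ratios on log site prevalences,
    covariate-adjusted observed/expected risk ratios from a control-arm
    logistic model, unpaired t-test sensitivity analysis, between-cluster
    coefficient-of-variation estimation, propensity-score matched
    exposure analysis, design-stage precision calculations, and a
    synthetic trial generator for end-to-end validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
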