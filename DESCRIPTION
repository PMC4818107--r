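Package: pathbias
Title: Logic-Gate Growth Models and Pathway-Bias Classification for
    Dose-Combination Response Surfaces
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits logic-gate models of cell growth regulation to AKT/MEK
    inhibitor dose-combination response surfaces by particle swarm
    optimization, selects model structures by AIC, and summarises each
    surface as a Pathway Bias statistic quantifying relative dependence on
    PI3K/AKT versus MAPK/ERK signalling. Includes a leave-one-out
    cross-validated logistic classifier of bias from protein biomarkers with
    permutation-based significance, biomarker-stratified rank-sum screens
    with hypergeometric gene-set enrichment, and a synthetic data generator
    emulating dose-response panels of HER2-amplified cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
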