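Package: glycorisk
Title: Serum N-Glycome Analysis of Alcohol Risk Drinking
Version: 0.1.0
Authors@R:
    person("Glycomics", "Pipeline Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for evaluating the serum N-glycome as a
    diagnostic marker of alcohol risk drinking. Covers chromatogram
    reduction (dextran-ladder glucose-unit calibration, 46-peak binning,
    closure to percent of total area), derived glycan trait computation
    (sialylation, galactosylation, branching, oligomannose, fucosylation),
    sex-stratified univariate screening with sequential Bonferroni
    adjustment, compositional log-contrast balance selection with
    cross-validated model-size choice, and diagnostic marker evaluation
    (sensitivity, specificity, likelihood ratios, covariate-adjusted
    ROC/AUC with DeLong confidence intervals). Ships a synthetic cohort
    generator emulating the compositional structure of a general-population
    glycomics study, so the full pipeline is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
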