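Package: fmdlag
Title: Distributed-Lag and Polygenic Mixed-Model Analysis of Particulate
    Air Pollution and Flow-Mediated Dilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying long-term particulate-matter exposure and
    brachial-artery endothelial function in family-based cohorts.  Computes
    flow-mediated dilation and shear-stress metrics from raw vascular
    measurements, builds date-indexed moving-average and monthly lag
    exposure metrics from residential concentration histories, fits linear
    mixed models with a pedigree-derived additive relationship matrix
    ("polygenic" models) by restricted maximum likelihood, and assesses the
    time course of exposure effects with polynomial distributed-lag models
    of orders 0 to 5 combined by BIC-weighted Bayesian model averaging.
    Includes a synthetic cohort generator (multi-generation pedigrees,
    kinship-correlated outcomes, seasonal monthly exposure series) so the
    full pipeline can be exercised and validated without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
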