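Package: angiokir
Title: Kinome Regression Analysis of Growth-Factor-Driven Endothelial
    Proliferation Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of time-lapse endothelial-cell
    proliferation screens. Estimates per-capita proliferation, birth and death
    rates from nuclei and dead-cell counts per well; fits exponential growth
    models and smoothed time-dependent rate curves; deconvolves kinase-inhibitor
    polypharmacology into per-kinase contributions by elastic-net kinome
    regression (KIR) against biochemical inhibition profiles; intersects ranked
    kinase lists across growth factors by rank sum; and evaluates siRNA
    validation experiments with control-normalized effects and many-to-one
    multiple-comparison testing. Includes a seeded stochastic simulator of
    384-well screens (quiescence exit, semi-synchronous division waves,
    apoptosis) with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
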