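Package: chemomarker
Title: Chemical-Marker Screening for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for screening chemical markers that
    discriminate two groups of samples in untargeted LC-MS metabolomics:
    QC-based feature filtering (relative standard deviation and 80-percent
    presence rules), Pareto scaling, per-feature Student's t screening with
    clustered heat-map matrices, cross-validated PCA, a from-scratch OPLS-DA
    with VIP scores, S-plot coordinates and SIMCA-style permutation
    validation, an iterative random-forest importance-aggregation selection
    procedure (cumulative top-N and top-1 frequency), and formula-based
    monoisotopic adduct m/z and neutral-loss annotation for negative-mode
    electrospray. Ships a synthetic feature-table generator with planted
    ground truth so every stage is testable end to end, plus packaged
    compound tables for two officinal Gentiana species.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
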