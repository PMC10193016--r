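Package: molscreen
Title: Machine Learning Screening for Scarce Bioactivity Data with
    Fragment-Based Augmentation and Dose-Response Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A ligand-based virtual screening toolkit for targets with very
    few known effectors. Seed actives and inactives are expanded by
    conservative fragment replacement at environment-matched sites
    (continuous structure-activity-relationship augmentation), featurized
    as concatenated extended-connectivity and MACCS fingerprints plus seven
    Z-scored physicochemical properties, and used to train binary
    bioactivity classifiers with explicit generalization-gap diagnostics.
    Unlabeled drug libraries are triaged by class probability, Tanimoto
    similarity-network neighbor counts, and drug-likeness property filters;
    nominated hits are validated by four-parameter logistic fitting of
    concentration-response assay data (IC50, maximal inhibition, R-squared
    activity calls). A synthetic data generator emulating a continuous SAR
    around drug-like scaffolds makes the full pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    stats,
    utils,
    tools,
    ranger,
    e1071,
    glmnet,
    class,
    pROC,
    igraph,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
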