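Package: diallelCRL
Title: Predicting Hybrid Metabolite Heterosis and Biomass from Parental
    Profiles in Diallel Crosses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deducing hybrid metabolite phenotypes and biomass from
    parental metabolite profiles in full reciprocal diallel designs. Hybrid
    metabolite levels are re-encoded relative to both parents as Combined
    Relative Level (CRL) class labels (additivity, dominance, overdominance)
    using moderated t-statistics with empirical-Bayes variance shrinkage.
    Parental-profile predictability of the labels is screened against
    permuted-label nulls by repeated stratified cross-validation over five
    classifier families; parental features are then ranked globally by
    aggregated SVM feature-weight ranks, and the ranking is validated by
    predicting hybrid root biomass with support vector regression against
    block-permutation nulls. Includes a synthetic diallel metabolome generator
    with known ground truth, GC-MS style normalization (log transform,
    two-factor batch correction, studentized-residual outlier removal,
    median sample scaling), and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mixOmics,
    withr
Config/testthat/edition: 3
biocViews: Metabolomics, Classification, Regression, FeatureExtraction,
    Normalization
RoxygenNote: 7.3.3
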