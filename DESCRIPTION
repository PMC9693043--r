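Package: NMRScreen
Title: 1H-NMR Metabolomics Screening of Two-Group Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for 1H-NMR metabolomics of two-group longitudinal
    cohorts: spectral preprocessing (apodization and Fourier transform,
    chemical-shift calibration, exclusion masking, fixed-width binning,
    total-area and probabilistic-quotient normalization), latent-variable
    modelling (PCA, PLS-DA and OPLS-DA with Pareto scaling, stratified
    cross-validation, permutation testing and CV-ANOVA), differential
    metabolite screening combining correlation loadings, VIP, fold change
    and t-test p values into volcano datasets and masked report tables,
    and hypergeometric pathway over-representation. Includes a synthetic
    cohort generator with planted effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
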