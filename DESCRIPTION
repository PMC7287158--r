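Package: mvdecode
Title: Multivariate Pattern Decoding for Multi-Dimensional Neuroimaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifiers and regression models for multivariate pattern
    analysis (decoding) of EEG/MEG/fMRI-style data: shrinkage-regularized
    linear discriminant analysis with automatic Ledoit-Wolf estimation,
    Gaussian naive Bayes, penalized logistic regression, support vector
    machines trained by dual coordinate descent, kernel Fisher discriminant
    analysis, and ridge / kernel ridge regression. A cross-validation engine
    with nested preprocessing and hyperparameter tuning sweeps analyses over
    arbitrary data dimensions, including temporal generalization
    (time-by-time decoding) and searchlight maps. Performance metrics,
    binomial and permutation tests, cluster-based permutation correction,
    and group-level (within- and between-subject) permutation statistics
    complete the pipeline. Seeded synthetic-data generators emulate epoched
    ERP-like trials, Gaussian class clouds, linear-model regression data and
    multi-subject metric maps so every component is testable without
    external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
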