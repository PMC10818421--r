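Package: ftirDA
Title: ATR-FTIR Fecal Spectral Fingerprinting with OPLS-DA and Classifier Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Chemometric analysis of attenuated-total-reflection Fourier
    transform infrared (ATR-FTIR) absorbance spectra of clinical samples.
    Provides a SummarizedExperiment-based container for replicate spectra on a
    uniform wavenumber grid, a synthetic cohort simulator with Gaussian
    absorption bands and planted group effects, spectral preprocessing
    (replicate averaging, evanescent-wave ATR correction, Savitzky-Golay
    derivatives, area/min-max/amide/vector normalization, Pareto and
    unit-variance scaling), a from-scratch OPLS-DA engine with permutation-test
    validation, CV-ANOVA and VIP scores, a multi-algorithm classification
    benchmark (logistic regression, KNN, decision tree, random forest, SVM)
    with stratified sample-grouped cross-validation and site-based external
    validation, and univariate spectral-marker selection combining VIP,
    Student's t-tests and fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    signal,
    glmnet,
    e1071,
    rpart,
    randomForest,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
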