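Package: BoolMark
Title: Boolean-Algebra Derivation of Predictive Biomarker Panels and
    Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-phase framework for discovering compact predictive
    biomarker panels from expression profiling of drug-treated samples.
    Phase one couples a multi-class linear support vector machine,
    evaluated under repeated stratified holdout, with drop-out importance
    scoring, greedy forward feature selection and exhaustive panel
    enumeration to identify small feature sets that maximise response
    classification accuracy. Phase two binarizes the expression of the
    selected markers, summarises each response group as a truth table, and
    applies exact Quine-McCluskey minimization with Petrick cover
    selection to derive response-group-specific expression signatures
    that can stratify new samples. Includes a synthetic pharmacoproteomic
    cohort generator with planted discriminative features for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    pROC,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Proteomics, BiomedicalInformatics
RoxygenNote: 7.3.3
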