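Package: metaboratio
Title: Metabolite-Ratio Biochemical Phenotyping of Targeted Plasma Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for blood biochemical phenotyping on 186-analyte targeted
    metabolomics panels (p180-style): a panel schema with a lipid-nomenclature
    parser and dialect-tolerant table I/O, a declarative catalog of the
    metabolite sums, quotients and enzyme-activity proxy equations used in
    glutaminolysis/MYC and inborn-error-of-metabolism screening (including the
    two-feature breast-cancer signature equation), evaluation machinery for
    univariate screening with false-discovery-rate control, ROC/AUC with
    Youden operating points, Monte-Carlo cross-validation with balanced
    subsampling, permutation testing and bootstrap confidence intervals, a
    packaged lactate/pyruvate logistic risk model, and a synthetic
    case/control/continuum cohort generator encoding published reference
    levels and effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
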