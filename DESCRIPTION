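Package: marelife
Title: Lifetime Foaling Rate and Pedigree-Based Genetic Evaluation for
    Horse Studbooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs a lifetime foaling rate (LFR) for brood mares at a
    fixed six-breeding-season endpoint from studbook reproductive records,
    projecting incomplete careers with coefficient- or regression-based
    predictors validated by percentage squared bias, mean absolute deviation
    and residual standard deviation.  Estimates genetic parameters for the
    trait with a pedigree-based animal model (herd, additive and dominance
    random effects) by EM/AI-REML, including the numerator and dominance
    relationship matrices, inbreeding coefficients, heritability with
    delta-method standard errors, BLUP breeding values, standardized EBVs,
    progeny-based accuracies, rank correlations and annual genetic trends.
    A seeded synthetic studbook generator with known true genetic parameters
    makes the whole pipeline testable without breed-association data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
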