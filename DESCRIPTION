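Package: qsarppr
Title: QSAR Modelling by Best Multi-Linear Regression and Grid-Search
    Projection Pursuit Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds quantitative structure-activity relationship (QSAR)
    models of compound potency (pIC50) from molecular descriptor tables.
    Provides descriptor-table reading, variance and collinearity pruning,
    reproducible train/test splitting, a best multi-linear regression
    (BMLR) beam search with a delta-R-squared breakpoint stopping rule,
    a projection pursuit regression (PPR) engine with df-matched spline
    ridge smoothers and staged refitting levels, multi-factor grid search
    over PPR hyperparameters under k-fold cross-validation, a PCA split
    diagnostic, calculators for graph and geometry descriptors (leading
    adjacency eigenvalue, first-order structural information content,
    principal moments of inertia), and a synthetic descriptor-table
    generator with planted linear and ridge structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
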