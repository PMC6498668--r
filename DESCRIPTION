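Package: jointnet
Title: Joint Inference of Differential Gene Networks from Two-Condition
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Jointly infers two sparse gene regulatory networks from gene
    expression data collected under two conditions (for example tumor and
    normal tissue) and identifies the edges that differ between them. Each
    gene is regressed on all other genes in both conditions simultaneously
    under an l1 penalty on the coefficients and a fused l1 penalty on their
    between-condition differences; the resulting convex problem is solved
    exactly by a proximal gradient algorithm whose per-coordinate proximal
    step is the closed-form two-variable fused lasso signal approximator.
    Includes penalty-path construction (lambda-max formulas, geometric
    grids), five-fold cross-validation with the two-standard-error rule,
    stability selection with edge-frequency ranking, simulators for paired
    regression problems and paired gene networks, gene filtering, and
    precision-recall evaluation of changed-edge rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'evaluate.R'
    'simulate.R'
    'solver.R'
    'lambda.R'
    'network.R'
    'selection.R'
    'benchmark.R'
    'io.R'
    'jointnet-package.R'
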