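Package: l1mrl
Title: Penalized Multistage Ramp Loss Learning for Dynamic Treatment
    Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns optimal multistage dynamic treatment regimens with
    simultaneous cross-stage variable selection by minimizing a
    group-lasso-penalized multistage ramp loss (L1-MRL).  The nonconvex
    surrogate is optimized by a difference-of-convex (DC) algorithm whose
    convex subproblems are solved by cyclic coordinate descent with exact
    piecewise-linear line search.  The package also provides the
    sequential comparison learners built on the same ingredients
    (lasso-penalized Q-learning, L1-penalized outcome-weighted learning
    solved as linear programs, and augmented outcome-weighted learning),
    AIC-type tuning by cross-validation, inverse-probability-weighted
    value estimators, and a SMART-style simulation benchmark with
    selection-accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    MASS,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
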