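Package: sparsefa
Title: Penalized Single- and Multiple-Group Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Penalized maximum-likelihood estimation of single- and
    multiple-group linear factor analysis models. Sparsity of the loading
    matrix and cross-group invariance of loadings and intercepts are induced
    through differentiable local approximations of the lasso, adaptive lasso,
    scad and mcp penalties. Models are fitted with a trust-region algorithm
    using analytic score and Fisher information; model complexity is measured
    by influence-matrix effective degrees of freedom and models are compared
    with a generalized Bayesian information criterion. Tuning parameters can
    be estimated automatically by minimizing an unbiased-risk (approximate
    AIC) criterion, or selected by grid search. A simulation harness
    generates factor-model data under known sparse population structures and
    computes Monte-Carlo performance summaries (MSE, squared bias, true and
    false positive rates, proportion choosing the true model).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    MASS,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
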