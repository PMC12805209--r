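Package: lcmshrink
Title: MSE-Optimal Regularized Estimation of Between-Group Effects in
    Two-Level Latent Covariate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the between-group (contextual) slope in two-level
    latent covariate models. Implements the maximum likelihood estimator
    based on the ANOVA decomposition of balanced grouped data, a regularized
    Bayesian (Stein-type) shrinkage estimator whose gamma-prior parameters
    are selected automatically by minimizing an analytic estimate of the
    mean squared error derived from gamma/F approximations to the sampling
    distributions of the between-group (co)variance estimators, analytic and
    delete-d jackknife standard errors, a balanced two-level data simulator
    indexed by intraclass correlations, and a Monte-Carlo study engine that
    compares estimators by RMSE and relative bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
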