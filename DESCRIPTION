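Package: foliarmap
Title: Species-Level Continuous Foliar Cover Mapping from Plots and Gridded Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tundra landscapes and line-point-intercept vegetation
    plots, computes terrain, hydrographic and multi-season spectral covariates
    on 30 m grids, delineates a statistically representative study area with a
    one-class boundary and moving-window rule, fits composite (hurdle)
    presence-classifier plus cover-regressor models with gradient boosting
    under nested 10-fold cross-validation and Gaussian-process Bayesian
    hyperparameter optimization, and evaluates continuous cover maps against
    categorical-map baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    xgboost,
    e1071,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
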