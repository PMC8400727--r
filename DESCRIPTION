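Package: jdsnmf
Title: Joint Deep Semi-Non-Negative Matrix Factorization for Multi-Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint, multi-layer, non-linear semi-non-negative matrix
    factorization (JDSNMF) for integrating several sample-matched or
    feature-matched data matrices. Decomposes the matrices into one shared
    latent matrix plus per-block hierarchical latent matrices linked by a
    non-linear activation, fitted by Adam gradient descent from an SVD
    initialization with early stopping. Includes a classical
    multiplicative-update NMF baseline, z-threshold construction of
    sample/feature modules from the first-layer latents, a logistic
    multi-view simulation benchmark with classifier-based evaluation, and
    module interpretation tools (local-surrogate importance, random-forest
    importance, covariate-adjusted age regression, and Fisher gene-set
    overlap tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
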