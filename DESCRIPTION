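Package: cdlvq
Title: Sex-Stratified Angle-GMLVQ Classification of Emotion-Processing
    Profiles in Conduct Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for distinguishing conduct-disordered
    (CD) from neurotypical youth with prototype-based machine learning on
    emotion-processing task scores. Provides a synthetic cohort generator
    with latent-factor correlation structure and sex-specific deficit
    patterns, covariate residualization (age, IQ, SES, site) to per-stratum
    z-scores, an angle-based Generalized Matrix Learning Vector Quantization
    (Angle-GMLVQ) classifier with learned feature relevances, a repeated
    holdout resampling engine with macro-averaged accuracy and related
    metrics, feature-relevance ranking across resamplings, and non-parametric
    comparison of female versus male classification models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
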