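Package: nichefactor
Title: Factorial Comparison of Climatic and Edaphic Predictor Sets in
    Ecological Niche Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for factorial experiments on ecological
    niche models (ENMs) that compare climate-only, soil-only (edaphic) and
    combined predictor sets across four algorithms (binomial GAM, maximum
    entropy with linear and quadratic features, random forest, and RBF
    support vector machine). Includes a synthetic-world generator (Gaussian
    random fields with controlled autocorrelation, virtual species with
    known Gaussian niches), occurrence cleaning and systematic thinning,
    principal-component predictor construction retaining more than 95% of
    variance, prevalence-1 pseudo-absence design with an adaptive
    checkerboard 2-fold spatial partition, threshold-dependent and
    independent accuracy metrics, a landscape shape index on binary maps,
    whole-map Kendall rank correlations, and repeated-measures factorial
    ANOVA with Mauchly's sphericity test and Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    e1071,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
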