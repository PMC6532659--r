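Package: glmmkat
Title: Kernel Association Tests for Correlated Microbiome Data via
    Generalized Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distance-based kernel association testing between microbial
    community composition and Gaussian, Binomial or Poisson host traits in
    family-based or longitudinal (clustered) study designs. Fits the null
    generalized linear mixed model by restricted maximum likelihood, using
    penalized quasi-likelihood for non-Gaussian traits, converts ecological
    distances (Jaccard, Bray-Curtis, unweighted/generalized/weighted
    UniFrac) into centred similarity kernels, computes variance-component
    score statistics, and calibrates p-values by block permutation over
    exchangeable clusters, combining candidate kernels through a min-p
    omnibus statistic. Also provides a Dirichlet-multinomial community
    simulator with within-cluster perturbation and experiment runners for
    type-I-error and power studies, plus standard preprocessing
    (rarefaction, abundance and depth filters) and principal coordinate
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    vegan
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
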