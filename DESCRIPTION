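Package: dispersr
Title: Dispersal Estimation from Georeferenced SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the mean per-generation dispersal distance (sigma) of a
    population from single-nucleotide polymorphism genotypes and per-sample
    geographic coordinates. Provides a continuous-space, individual-based
    forward simulator for generating training data with known dispersal, a
    pairwise convolutional feature extractor trained on those simulations
    (with gradient gating over sample-pairs to bound memory), evaluation
    metrics, and Rousset's classical isolation-by-distance regression as a
    baseline estimator.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
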