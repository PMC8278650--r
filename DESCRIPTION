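Package: autozyg
Title: Classifying Recent and Ancient Inbreeding from Pedigrees and Runs of
    Homozygosity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Partitions individual inbreeding into recent ("new") and ancient
    ("old") components from pedigree records and runs of homozygosity (ROH),
    and selects trait-specific classification thresholds by a grid search that
    compares the estimated inbreeding-depression effects of the two
    components.  Includes pedigree inbreeding coefficients with ancestral-path
    truncation (changing base generation), deterministic ROH detection with
    density and heterozygote filters, Monte-Carlo gene dropping for
    Kalinowski-style ancestral inbreeding, two-component Gaussian mixture
    classification of segment lengths, pedigree BLUP depression regressions
    via Henderson's mixed-model equations, model comparison criteria, and a
    closed-herd simulator with recombination and age-annotated identity by
    descent that serves as a fully synthetic test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
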