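Package: microherit
Title: Heritability of Host-Associated Microbiome Traits in Clonal Pedigreed Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of amplicon (ASV) count tables from
    clonally replicated, pedigreed field trials. Provides pedigree validation
    and the tabular-method additive relationship matrix, a seeded generator of
    complete synthetic studies (pedigree, incomplete-block trial layout, soil
    covariates, gene-dropped genetic values, negative-binomial ASV counts),
    rarefaction and core-microbiome filtering, thin-plate-spline spatial
    correction of transformed counts, nested PERMANOVA with Type I sums of
    squares and permutation of residuals under a reduced model, PERMDISP
    dispersion tests, and per-ASV average-information REML estimation of
    additive, family, and non-additive variance components with broad- and
    narrow-sense heritability, delta-method standard errors and z-score
    significance calls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
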