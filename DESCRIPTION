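Package: onepot
Title: One-Pot Single-Cell eQTL Mapping in Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for expression quantitative trait locus (eQTL) mapping from
    a single pooled single-cell RNA-seq experiment on a segregating yeast
    population. Each recombinant cell is genotyped genome-wide from sparse
    allelic UMI counts with a two-state hidden Markov model; local and distant
    eQTLs are mapped with negative-binomial generalized linear models, LOD
    scores, 1.5-LOD-drop confidence intervals and a permutation-based false
    discovery rate; eQTL-by-cell-cycle interactions are tested by contrasting
    stage-specific effects; allele-specific expression and allele-specific
    expression noise (negative-binomial overdispersion) are quantified in F1
    hybrids; loci shifting cell-cycle stage occupancy are mapped by logistic
    regression; and trans-eQTL hotspots are detected by Poisson tests on
    genomic bins. A full synthetic-data generator emulates recombinant
    genotypes, UMI counts with planted eQTL, batch and cell-cycle structure,
    allelic reads with sequencing error, doublets, and F1-hybrid allelic
    counts, so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    jsonlite,
    optparse,
    yaml,
    readr,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
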