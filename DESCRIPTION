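Package: panmixsel
Title: Forward-in-Time Simulation of Recurrent Genomic Selection in
    Panmictic Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of recurrent genomic
    selection in panmictic (random-mating) animal breeding populations.
    Builds multi-chromosome genomes with SNP panels and QTL, engineers
    founder linkage disequilibrium by crossing divergent parental
    populations, simulates additive-dominance traits with optional
    constrained digenic epistasis (classical two-locus F2 patterns) and
    the Kempthorne orthogonal variance partition, tracks founder-allele
    identity by descent through map-based meiosis, and evaluates
    candidates by GBLUP or pedigree BLUP using AI-REML with VanRaden
    additive, Su dominance and Hadamard epistatic kernels. Eight
    selection schemes (truncation on predicted additive value, true
    genotypic value, pedigree BLUP and random-mating controls) are run
    over replicated selection cycles, with per-generation gain,
    genotypic variance, prediction accuracy, pedigree, genomic and
    realized inbreeding, selected-family counts and favorable-allele
    frequency summaries returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rlang,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
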