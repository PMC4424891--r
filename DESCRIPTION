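Package: gselsim
Title: Simulation of Sequence- and Array-Based Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A coalescent plus gene-dropping simulator for comparing genomic
    selection strategies. Founder haplotypes are generated under a
    bottlenecked coalescent calibrated to a target nucleotide diversity,
    quantitative trait nucleotides with additive and dominance effects are
    placed inside predefined gene windows, and genomes are dropped through a
    multi-generation breeding pedigree. Predictor panels (ascertained SNP
    arrays, RAD windows, whole sequence, causal sites, gene-region priors)
    are evaluated with pedigree BLUP, SNP-BLUP and VanRaden's nonlinear A
    model, scored by cross-validation accuracy in the last generation.
    Genotyping, sequencing and imputation error models are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    vcfR,
    withr
Config/testthat/edition: 3
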