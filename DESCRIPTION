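Package: phyloallele
Title: Bayesian Phylogenetic Prediction of Unobserved Alleles and Genotype Phasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places experimentally verified alleles of a long gene locus in a
    Bayesian coalescent phylogeny, enumerates candidate ancestral (predicted)
    alleles at internal nodes with posterior probabilities, and uses the
    combined observed-plus-predicted allele catalogue to phase unphased
    diploid genotypes with quantified confidence. Includes a TN93
    substitution model with Felsenstein pruning likelihood, a constant-size
    coalescent tree prior, a Metropolis-Hastings sampler over time-trees,
    maximum clade credibility summaries, joint stochastic ancestral state
    sampling, a coalescent sequence simulator with known truth, and a
    command-line front end for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
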