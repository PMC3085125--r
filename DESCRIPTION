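Package: jostdiv
Title: Allele-Based Diversity and Differentiation for Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative population-genetic analysis of highly variable
    markers: effective number of alleles, observed/expected heterozygosity
    and nucleotide diversity; Jost's D, G_ST and gamma_ST differentiation
    with individual-level permutation tests; Chakraborty null-allele
    estimation; exact-binomial sign aggregation of per-locus expansion
    statistics; fragment-length power analysis for sequence data;
    pairwise-D neighbour-joining trees and Mantel isolation-by-distance.
    Includes a forward-time finite-island Wright-Fisher simulator
    (stepwise, infinite-alleles and finite-sites mutation) so every stage
    of the pipeline can be exercised on data with known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    geosphere,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
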