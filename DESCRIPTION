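Package: svscape
Title: Repeat-Aware Characterization of Structural-Variant Landscapes in
    Multi-Community Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify insertion and deletion variants by their local
    repeat context (homopolymer, short tandem repeat, tandem repeat, and
    interspersed mobile-element families) using extended local allele
    sequences, and to characterize a joint-genotyped callset across a
    multi-community cohort: sharedness and geographic labels, novelty against
    external annotation sets by graded reciprocal overlap, discovery curves,
    telomere-distance density, gene-constraint (LOEUF decile) densities, short
    tandem repeat expansion discovery and diploid genotyping, Bray-Curtis
    principal coordinate analysis and Weir-Cockerham fixation indices. A
    synthetic cohort generator with Balding-Nichols population structure and
    planted repeat variants provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    S4Vectors,
    generics,
    ggplot2,
    IRanges,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
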