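Package: divcover
Title: Genome Representation of rRNA-Defined Diversity from Constrained Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures how much of a clade's SSU rRNA (16S) diversity is
    represented by sequenced genomes. Merges rRNA sequences from reference,
    genome-derived and culture-collection sources with lineage-congruence and
    genome-usability filters, dereplicates them into OTUs by greedy identity
    clustering with asymmetric coverage control, extends a curated seed
    alignment by consensus threading, trims alignment columns by entropy and
    gap content, builds a phylogeny whose induced topology preserves a
    backbone constraint tree via OLS minimum-evolution insertion and
    constrained NNI, and computes a per-clade sequenced genome fraction with a
    strict <1 percent "unsequenced" classification. A synthetic-data module
    generates complete studies (Yule species tree, HKY sequence evolution,
    clade-structured genome availability) with known truth so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
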