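Package: msabias
Title: Simulation Study of Alignment Uncertainty in Phylogenetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how multiple sequence alignment (MSA) error biases
    downstream maximum-likelihood phylogenetic inference. Simulates nucleotide
    (GTR+Gamma) and amino-acid (WAG+Gamma) sequences with a reversible indel
    process on designed trees while recording the true alignment, provides a
    self-contained progressive aligner, alignment-distance and homology-pair
    accuracy metrics, maximum-likelihood branch-length and topology inference
    with a RELL-based Shimodaira-Hasegawa test, Fitch parsimony, and
    experiment drivers for divergence bias, OTU scaling, polytomy resolution
    and Felsenstein-zone long-branch-attraction grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
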