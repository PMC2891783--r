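Package: treecarto
Title: Split-Space Embedding and Cartographic Projection of Phylogenetic Tree Space
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents unrooted binary phylogenetic trees as 0/1 vectors in
    split space (one coordinate per nontrivial bipartition), where all
    topologies on n taxa lie on a hypersphere of squared radius n - 3, and
    projects them to two or three dimensions with a linear, hash-table-backed
    cartographic projection that runs in O(n) per tree.  Includes exhaustive
    topology enumeration, Robinson-Foulds distances, majority-rule consensus,
    a stress-majorization MDS baseline, a neighborhood-consensus locality
    experiment, Fitch parsimony with TBR/NNI rearrangement search, a
    synthetic alignment simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
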