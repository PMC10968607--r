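Package: loxtype
Title: Classification and Regiospecificity Prediction of Diatom Lipoxygenases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize putative lipoxygenase (LOX) enzymes from
    diatoms. Curates candidate protein sequences by iron-coordination-site
    rules, locates and classifies the five-residue cofactor coordination
    pattern into sequence groups, clusters sequences with neighbor-joining
    trees and bootstrap clade support, extracts the geometry of an
    enzyme-substrate pose (iron position, fatty-acid carbon chain, oxygen
    channel gate) from PDB structures, and predicts LOX regiospecificity from
    the nearest-carbon rule with oxygen-channel gating. Includes seeded
    generators for synthetic sequence and pocket fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
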