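Package: enzrepo
Title: Enzyme Re-Positioning by Reaction Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens for alternative enzyme genes across taxa by similarity of
    the chemical transformations reactions perform, rather than by gene
    sequence similarity. Reactions are compared through RDM reaction-center
    patterns (atom-type changes at the Reaction center, in the Difference
    region, and in the Matched region) extracted from maximum-common-subgraph
    atom mappings between substrate and product. Taxon-specific reactions
    (including orphan-enzyme reactions) are identified from ortholog-cluster
    membership, scored against all reactions of a target taxon, and candidate
    genes are reported, profiled phylogenetically, and checked for sequence
    independence by local protein alignment. Includes a seeded generator of
    synthetic reaction databases with planted cross-taxon analog reactions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Biostrings,
    ape,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse
Config/testthat/edition: 3
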