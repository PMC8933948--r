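Package: spliceortho
Title: Splicing-Structure Orthology and Spliced CDS Ortholog Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the coding structure of genes and transcripts as ordered
    token strings of functional sites (start and stop codons, splice donors
    and acceptors) and coding blocks. Pairwise alignment of tokens between
    orthologous genes establishes token orthology, predicts unannotated
    splice sites and coding blocks, and tests whether a spliced CDS known in
    one species is expressible and executable in another. Three-species gene
    triplets are classified with functional-site and transcript graphs into
    structurally orthologous genes and CDS orthology groups, predicted CDSs
    are written as GTF, and predictions are tagged with annotation- and
    splice-junction-based evidence. Includes a deterministic generator of
    tri-species synthetic gene fixtures (FASTA, GTF, junction files).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
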