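Package: asvgraph
Title: Exact-Match Amplicon Sequence Variant Picking with Linked-Data
    Provenance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: De novo picking of amplicon sequence variants (ASVs) from
    paired-end marker-gene reads using exact forward/reverse sequence
    matching with a two-step, abundance-based error model: singleton
    rescue by a k-bounded Levenshtein distance with end-tolerant
    ("phantom" frame-shift) gap handling, and low-abundance ASV merging
    with provisional rejection rather than deletion.  Includes chimera
    flagging, rank-capped taxonomic assignment against a lookup table
    built from SILVA-style aligned or unaligned reference FASTA files,
    serialization of provenance-linked ASV objects to Turtle (RDF) and
    extended BIOM 1.0 JSON, cross-sample ASV tracking queries, binary
    classifier and modified RV evaluation metrics, and a deterministic
    mock-community generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    digest,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
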