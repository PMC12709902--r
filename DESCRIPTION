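Package: sgstop
Title: Guide RNA Design for Cytosine Base-Editor Gene Knockout via Premature Stop Codons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates candidate single-guide RNAs over an annotated bacterial
    coding sequence, retains only guides whose editing-window C-to-T conversions
    create an in-frame premature stop codon (Target-AID architecture by
    default), screens spacers for off-target matches against a genome FASTA,
    ranks and annotates viable guides, exports GFF3/BED/TSV reports, and emits
    cloning-ready oligos for single-component editor backbones. Includes a
    seeded synthetic-locus generator with ground-truth manifests for testing
    guide filters without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
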