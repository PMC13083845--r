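Package: spliceaudit
Title: Auditing Transgene Constructs for Cryptic Splice Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing plasmids, epitope tags, and linkers for
    cryptic splice sites before synthesis, and for verifying transcript
    fidelity afterwards. Scores candidate 5' (donor) and 3' (acceptor)
    splice sites with maximum-entropy log-odds models using the classic
    consensus-odds by table decomposition of MaxEntScan-style scorers,
    enumerates or samples synonymous codon encodings of peptide tags to
    profile their splice risk, designs splice-safe encodings by silent
    mutation, and quantifies aberrant splicing from spliced RNA-seq
    alignments mapped to the full plasmid sequence. Ships a synthetic
    first-order maximum-entropy splice model built from literature
    consensus base frequencies; genuine MaxEntScan table directories can
    be loaded in their native format when available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomeInfoDb,
    GenomicAlignments,
    methods,
    stats,
    utils,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
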