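Package: breakscan
Title: Mapping Activity-Induced DNA Double-Strand Breaks from gammaH2AX ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates gammaH2AX ChIP-seq signal (a chromatin proxy for DNA
    double-strand breaks) to stimulus-induced transcription in sorted neuronal
    and non-neuronal brain nuclei. Provides gene-body and peak signal
    quantification (RPKM), a two-tier broad-peak workflow with peak-to-gene
    annotation, cross-fraction differential grouping, hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction,
    position-weight-matrix motif scanning with nearest-TSS site annotation and
    anchored aggregate signal profiles, and an expression-matched permutation
    test that asks whether induced genes carry more break signal than expected
    from their expression level alone. A seeded synthetic-data generator
    emulates the statistical structure of the real inputs so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
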