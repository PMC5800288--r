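Package: zygopir
Title: P-Element Insertion-Site Calling and Zygotic piRNA Quantification
    for Hybrid Dysgenesis Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying paternal P-element genomics and
    zygotic piRNA production in Drosophila P-M hybrid dysgenesis. Calls
    P-element insertion sites from restriction-digest junction-library
    paired-end reads, estimates within-line insertion occupancy, annotates
    sites with piRNA-cluster membership (dual-strand/unistrand, active/low)
    and chromatin transcriptional state, types full-length (FP) versus
    internally deleted (KP) element variants with qPCR-style relative
    quantification, quantifies element-derived piRNAs from small-RNA reads
    with miRNA-based RPM normalization, and links these molecular
    measurements to gonadal-dysgenesis phenotypes through correlation,
    multiple regression and furthest-neighbor clustering. A synthetic-data
    module generates every input with recorded ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
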