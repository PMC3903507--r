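Package: mircot
Title: MicroRNA Discovery and Evolutionary Analysis from Plant Small RNA
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for annotating plant microRNAs from small RNA
    sequencing libraries: adaptor trimming and read collapsing, 0-mismatch
    genome mapping, sliding-window hairpin prediction with secondary-structure
    filtering, rule-based miRNA/miRNA* annotation with a processing-precision
    statistic, homoeolog retention analysis after whole-genome duplication,
    Kimura 2-parameter divergence dating with neighbor-joining trees, and
    Fisher's exact enrichment of miRNA targets in hierarchical functional
    bins. Includes a synthetic-data generator that plants miRNA hairpins in a
    toy genome and simulates Dicer-processed reads with a ground-truth ledger,
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
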