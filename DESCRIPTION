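Package: exonusage
Title: Junction-Based Exon Inclusion Analysis for Complex Multi-Exon Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies alternative splicing of large multi-exon genes
    (the titin TTN metatranscript being the flagship use case) from splice
    junction evidence. Extracts junctions from spliced SAM alignments,
    merges per-sample junction counts into a junction-by-sample matrix,
    classifies every junction against an exon/isoform model (canonical,
    exon skipping, alternative donor/acceptor), predicts reading-frame
    consequences, applies multi-sample quality-control filters with
    cross-cohort validation, computes a per-exon inclusion-rate statistic
    (a PSI-like value) with constitutive/variable categorisation, and
    scores splice-site windows with a position-frequency consensus value.
    A synthetic-data module simulates isoform mixtures, junction counts
    and spliced reads with known ground truth so every pipeline stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
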