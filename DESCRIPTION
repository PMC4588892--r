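Package: fsqtl
Title: Candidate-Gene Prioritization and Organ Morphometrics for the
    Tomato Fruit-Shape Locus fs8.1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for prioritizing candidate genes in a
    fine-mapped quantitative trait locus (QTL) interval, built around the
    tomato fruit-shape locus fs8.1. It extracts gene models from a mapped
    interval, applies RPKM expression and threshold-based differential
    expression filters across paired near-isogenic-line comparisons,
    localizes sequence variants relative to gene models and predicts
    protein-level consequences (missense, stop gained, stop lost with
    extension length), integrates the evidence into a candidate table,
    performs hypergeometric term enrichment, and computes organ
    morphometric statistics including shape index and dominance/additivity
    gene action. A seeded synthetic-study generator emits complete GFF3,
    FASTA, VCF, expression and phenotype fixtures with planted causal
    structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
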