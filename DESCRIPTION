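Package: tfrepertoire
Title: Rule-Based Transcription Factor Family Classification and
    Comparative Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies protein and translated-transcript sequences into
    transcription factor (TF) and transcriptionally active protein (TAP)
    families from protein-domain evidence using mandatory/forbidden domain
    rules with synonym resolution; merges discordant outputs of several
    family-identification pipelines into one non-redundant repertoire
    under a fixed source-priority rule; compares per-family repertoires
    between species with ratio bands and ploidy correction; runs an
    iterative multiple-alignment curation loop (sequence coverage, gap
    column and near-duplicate filters to a fixed point); labels tree
    leaves with clades via reference anchor sequences; and links
    repertoire members to reference-transcript expression (FPKM) via
    best-hit tables. A seeded synthetic-data generator builds proteomes
    with planted domain architectures, domain-hit tables, pseudo-pipeline
    outputs and expression matrices with known ground truth, so the whole
    workflow is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite
Config/testthat/edition: 3
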