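Package: allelert
Title: Allele-Resolved Replication Timing and Nascent Transcription Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for allele-resolved two-fraction (early/late)
    Repli-Seq and nascent-RNA (Bru-Seq) data from hybrid genomes. Computes
    binned log2(early/late) replication-timing profiles per allele,
    quantile-normalizes them to a wild-type reference, smooths and scales
    display tracks, quantifies a domain-level replication-timing advance
    statistic normalized to the wild-type allelic baseline with per-window
    permutation significance, quantifies nascent transcription and exact
    barcode abundances, and relates timing advances to transcription rates
    across experimental conditions. Ships a synthetic hybrid-genome data
    generator with full ground truth so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
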