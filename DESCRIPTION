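Package: pausenexus
Title: Reporter ChIP-Nexus Profiles and Paused Pol II Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing RNA polymerase II promoter-proximal pausing
    from ChIP-nexus exonuclease stop-base data on reporter plasmids and genomic
    promoters. Builds strand-separated stop-base profiles from barcoded aligned
    reads (unique-alignment filtering, barcode deduplication, reads-per-million
    normalization), quantifies paused Pol II stability after triptolide
    treatment (windowed total signal, retention ratios, single-timepoint
    half-life back-calculation), annotates core promoter elements (TATA box,
    initiator and downstream pausing elements) by positional IUPAC consensus
    matching, stratifies paused Pol II half-lives by element combinations with
    rank-sum statistics, and computes sequence-composition summaries (position
    frequency matrices, information content, base frequencies at the +2
    position). A synthetic-data generator produces promoter cohorts, reporter
    reads and qPCR tables with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
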