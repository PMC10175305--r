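Package: cpdfootprint
Title: Base-Resolution UV Damage Footprinting from CPD Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of targeted cyclobutane pyrimidine dimer (CPD)
    sequencing data for UV damage footprinting of protein-DNA
    interactions. Converts deduplicated mate-1 alignment records into
    strand-aware per-base CPD counts at dipyrimidine sites, computes
    per-position cellular versus naked-DNA damage fold changes with
    negative-binomial exact tests, local-window and dinucleotide-class
    normalization, extracts transcription-factor damage signatures at
    motif matches, classifies binding-site occupancy with a
    nearest-neighbor rule, aggregates signatures from sparse genome-wide
    detections, and includes a synthetic data generator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
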