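Package: submotifr
Title: Divide-and-Conquer Decomposition of Transcription Factor Binding
    Motifs into Submotif Families
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes a transcription factor's binding-site collection
    into hierarchically organized submotif families using possibilistic
    fuzzy c-means clustering with Xie-Beni model selection, encodes each
    submotif as a position weight matrix, combines submotifs into an
    OR-voting multi-classifier whose thresholds and composition are tuned
    by a genetic algorithm under a multi-objective accuracy/complexity
    fitness, optionally fuses submotif scores with fuzzy promoter-distance
    rules, scans annotated genomes for binding sites, calls ChIP-chip
    peaks, and profiles per-position rates of binding-site evolution under
    the Halpern-Bruno model against an HKY85 background.  Ships a seeded
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    S4Vectors,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
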