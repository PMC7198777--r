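Package: replimode
Title: Replication Origin and Replication-Mode Inference for Circular
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers replication origins and population replication modes of
    circular bacterial (especially cyanobacterial) chromosomes. Computes
    windowed and cumulative GC and CDS (gene-orientation) skew profiles with
    rotation-invariant shift-point detection and a V-shape regularity score;
    performs marker frequency analysis (MFA) on exponential- versus
    stationary-phase sequencing coverage, including read quality trimming,
    bedGraph depth aggregation, two-scale depth-ratio profiles, origin
    detection and single-origin / multi-origin classification; estimates
    chromosome copy number (ploidy) from flow-cytometry fluorescence ratios
    against a reference species; and bundles a seeded simulator of skewed
    genomes, biased gene sets, replication-fork coverage under single-origin,
    multifork and asynchronous multi-origin models, and per-cell fluorescence
    distributions, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
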