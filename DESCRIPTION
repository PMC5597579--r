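Package: spikechip
Title: Spike-In Calibrated ChIP-Seq Normalization and Centromeric Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis toolkit for spike-in (ChIP-Rx) calibrated
    ChIP-seq, motivated by studies of chromatin-remodeler-driven histone H3
    eviction at fission-yeast regional centromeres. Implements the spike-in
    normalized IP/input ratio and its scaling factors, signal extraction
    scaling (SES) for samples without spike-in, normalized fold-change tracks
    and region fold-enrichment statistics, scaled-region metagene profiling
    with exact 1-D two-means classification and hypergeometric gene-set
    overlap tests, and a per-division minichromosome loss-rate estimator.
    A dual-genome synthetic read-count generator with an analytic expectation
    mode makes every stage testable end-to-end without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
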