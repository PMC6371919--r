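Package: cohesintools
Title: Spike-In Calibrated ChIP-Seq and Cohesin Ring Entrapment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis toolkit for quantitative cohesin biology.
    Implements spike-in calibrated ChIP-seq processing (sequential two-genome
    read assignment, occupancy-ratio normalization, zero-filled per-base
    coverage pileups, and centromere-anchored averaged meta-profiles), a
    combinatorial stoichiometry model of cohesin-ring circularization that
    predicts catenated-monomer and catenated-dimer detection in the
    minichromosome IP assay (ring versus handcuff discrimination), gel-lane
    densitometry summaries, and phosphate-release ATPase rate estimation from
    a KH2PO4 standard curve. A synthetic-data module generates genome pairs
    with unique k-mers, enrichment-profiled IP/WCE read sets, simulated gel
    lanes, and absorbance time series so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
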