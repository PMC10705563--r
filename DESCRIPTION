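Package: m6Afootprint
Title: Single-Molecule Chromatin Footprinting from m6A Methyltransferase
    Base Calls
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts per-molecule N6-methyladenine (m6A) base calls from
    methyltransferase (M.EcoGII) accessibility footprinting of long reads
    into per-base-pair chromatin state calls (nucleosomal, accessible or
    ambiguous) on each DNA molecule. An adjusted binomial sliding-window
    test corrects for m6A detection inefficiency and AT-content calling
    bias via a per-window-AT-count linear calibration fitted on a
    fully-methylated purified-DNA control, with per-read Benjamini-
    Hochberg correction and boundary-resolution rules. Population-level
    summaries include nucleosome phasing relative to transcription start
    sites, occupancy, and a per-gene nucleosome-position heterogeneity
    score based on pairwise correlation of single-molecule state vectors.
    A synthetic-read simulator with ground-truth footprints supports
    calibration, threshold selection and in-silico validation with
    ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    data.table,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Epigenetics, NucleosomePositioning, SingleCell, Sequencing,
    Coverage
RoxygenNote: 7.3.3
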