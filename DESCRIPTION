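Package: SpliceDynamics
Title: Alternative-Splicing Event Detection and Psi Dynamics Across
    Developmental Time Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transcriptome dynamics across a developmental
    time series from transcript models and transcript-level TPM estimates:
    curation of assembled transcript annotations (expression floor,
    fragmented-transcript and precursor rules, coding-consensus
    classification), classification of transposon-derived transcripts against
    repeat annotations with positional PWM motif scanning, enumeration of the
    seven local alternative-splicing event types from isoform structures,
    percent-spliced-in (Psi) quantification with adjacent-time-point and
    tissue-pair rank tests, over/normal classification of retained-intron
    events at the zygotic-genome-activation transition, intron feature
    characterization (length, GC, relative position, splice-site and
    branch-point strength), and PCA variable contributions for PC-related
    transcript selection. Includes a fully seeded synthetic-data generator
    that plants gene models, splicing events, Psi trajectories, repeats and
    motifs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'SpliceDynamics-package.R'
    'annotation-io.R'
    'as-events.R'
    'intron-features.R'
    'pca-contrib.R'
    'pipeline.R'
    'psi-analysis.R'
    'synthetic-data.R'
    'te-catalog.R'
    'transcript-filters.R'
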