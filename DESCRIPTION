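Package: ParalogOccupancy
Title: Paralog-Specific Transcription-Factor Occupancy and Cofactor-Dependency Decomposition
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for detecting paralog-specific transcription-factor binding
    from replicated ChIP-seq designs and decomposing it by cofactor
    dependency. Implements position-specific affinity model (PSAM) scanning
    of genome sequence into normalized, thresholded, windowed-maximum
    affinity tracks; consensus-locus construction from replicate peak sets
    with summit re-centering; 100-bp locus occupancy scoring, cross-sample
    scaling and peak-centered signal matrices; negative-binomial
    differential-occupancy testing with Benjamini-Hochberg correction and
    membership-based locus classification; FDR-based cofactor-dependency
    ordering with high-confidence boundary calling; a simplified single-mode
    maximum-likelihood PSAM fitter for one-round SELEX read sets; and a
    synthetic-data generator that plants monomer, composite-dimer and
    spaced-dimer binding sites with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, DifferentialPeakCalling, MotifAnnotation, Transcription
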