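Package: trapline
Title: Mother-Machine Phenotyping and Sequential-FISH Genotyping on Synthetic Microscopy Fixtures
Version: 0.1.0
Authors@R: person("trapline", "developers", role = c("aut", "cre"),
    email = "trapline@example.org")
Description: An image-analysis pipeline for mother-machine microfluidics
    experiments that combine live-cell phenotyping with in situ genotyping.
    Provides a synthetic-data generator for trap time-lapse stacks with full
    ground truth, phase-contrast background subtraction and cell segmentation,
    Jaccard-scored lineage tracking with binary-fission divisions and
    lineage-quality filters, fast-radial-symmetry single-molecule spot
    detection with landmark-based two-camera registration, sequential-FISH
    barcode calling and redundancy-corrected genotype decoding per trap, and
    exact Clopper-Pearson sensitivity/specificity statistics plus bulk
    growth-curve and repression-ratio analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
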