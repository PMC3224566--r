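Package: maldiPanel
Title: Mean-Spectrum Peak-Region Preprocessing and Neural-Network Marker
    Ranking for MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Differential-marker discovery from raw MALDI-TOF mass spectra
    of two-class cohorts (e.g. serum or plasma peptide profiles).  Spectra
    are merged onto a common m/z grid, the cohort mean spectrum is encoded
    as a binary increase/decrease sign sequence, and peak regions are
    delimited by runs of ascent and descent signs with per-segment
    thresholds, then binned into a samples-by-peaks table labelled by
    median m/z.  A hybrid genetic-algorithm/feedforward-network reducer
    shrinks the peak set, a forward stepwise backpropagation network under
    Monte-Carlo cross-validation ranks candidate marker ions, and a
    50-sub-model ensemble classifies a held-out blind set with vote
    fractions, TPR/FPR and ROC/AUC.  A seeded synthetic-spectrum generator
    with known differential peaks supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'maldiPanel-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'simulate.R'
    'preprocess.R'
    'gann.R'
    'stepwise.R'
    'evaluate.R'
    'pipeline.R'
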