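Package: mitomorph
Title: 3D Mitochondrial Morphometry, Mitophagy Reporters, and Climbing
    Behaviour for Drosophila Dopaminergic Neurons
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for confocal studies of dopaminergic
    neuron mitochondria in Drosophila parkin mutants. Segments multi-channel
    3D z-stacks into mitochondrial objects within a tyrosine hydroxylase
    (TH)-defined region of interest, computes object volume, surface area,
    maximum Feret diameter and inverse sphericity (6V/DS), size-bin
    histograms and mitochondrial network volume per cell; quantifies
    MitoTimer red:green volume ratios, autophagosome puncta per cell and
    object-based Pearson colocalization (mitophagy initiation); analyses
    negative-geotaxis beam-break traces (height climbed, ROC threshold
    classification); normalizes western-blot lanes by total protein; and
    applies normality-gated comparison statistics. Ships a synthetic-data
    generator producing z-stacks, behavioural traces and lane tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    withr,
    multcomp,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, CellBiology, Visualization, Preprocessing
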