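Package: phosmet
Title: Phosphosite Functionality Screening by Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of untargeted flow-injection metabolomics
    screens of yeast phosphosite mutant panels. Corrects run-order signal
    drift by robust LOWESS, references ion intensities against OD-wise
    per-ion intensity curves (including a permutation-balanced variant for
    measurement batches dominated by a single mutant), calls differentially
    changing ions with Welch tests and Storey q-values, performs iterative
    expanding-subset hypergeometric pathway enrichment on deprotonated-ion
    annotations, quantifies mutant-pair and across-condition self
    correlations of metabolic profiles, fits microplate growth curves, and
    combines the evidence channels into a composite 0-9 phosphosite
    functionality score. Includes a synthetic-data generator that emulates
    the screen's design for calibration and spike-in recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Metabolomics, Software, Preprocessing, DifferentialExpression
RoxygenNote: 7.3.3
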