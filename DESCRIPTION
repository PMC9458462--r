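Package: inoscan
Title: Detection and Quantification of Inosine Misincorporation into RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and quantifying stochastic inosine
    misincorporation into RNA from sequencing and mass-spectrometry
    readouts. Computes per-position base substitution frequencies,
    per-base accuracies and between-condition enrichment from pileup
    statistics tables (direct RNA nanopore or short-read); performs
    depth-gated candidate-window substitution analysis with variant
    quality filtering; converts LC-MS/MS nucleoside levels (IMP per
    million AMP) to per-base incorporation rates and fits 1/x-weighted
    calibration curves; and quantifies translation from polysome
    absorbance traces (baseline normalization, valley boundary
    detection, trapezoid areas, polysome to monosome ratios). A
    synthetic-data generator emulates inosine-containing transcript
    populations and their sequencing, mass-spectrometry and polysome
    readouts so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    vcfR,
    multcomp,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
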