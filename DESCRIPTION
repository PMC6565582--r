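Package: fcscnv
Title: Fluorescence Correlation Spectroscopy Simulation and Fitting with
    22q11.2 Microduplication Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates confocal fluorescence correlation spectroscopy (FCS)
    photon-count traces from Brownian emitters in a 3D Gaussian observation
    volume (with optional two-state triplet blinking), estimates normalized
    temporal autocorrelation curves with direct and multi-tau correlators,
    fits multi-component free 3D diffusion models with triplet contribution,
    calibrates observation-volume geometry from a rhodamine 6G standard and
    converts fitted molecule numbers to concentrations.  Also provides pooled
    case-control enrichment statistics (odds ratio, Woolf confidence interval,
    Fisher exact test) for 22q11.2 microduplication carrier counts in bladder
    exstrophy cohorts, and 1-based genomic interval arithmetic with BED
    interchange for the duplication calls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
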