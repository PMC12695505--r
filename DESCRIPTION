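Package: qeegr
Title: Quantitative EEG Relative Band Power Analysis with Nonparametric
    Effect Sizes
Version: 0.1.0
Authors@R:
    person("qEEG", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantitative EEG analysis for multi-visit clinical
    cohorts: reading and preprocessing of resting-state recordings
    (BrainVision, EDF, plain-text matrix), Welch power spectral density,
    relative band power by frequency band and scalp zone, Cliff's delta
    effect sizes (unpaired and paired), a seeded resampling mixed-design
    ANOVA for group-by-visit comparisons, Spearman correlations with
    neuropsychological scores under Benjamini-Hochberg FDR control, and a
    synthetic cohort generator that emulates 1/f EEG with band-limited
    oscillations so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
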