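Package: mrcprel
Title: Rater Reliability Analysis for Movement-Related Cortical Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying the reliability of
    peak-negativity (PN) labelling in movement-related cortical potentials
    (MRCPs). Provides a synthetic-data generator for condition-specific MRCP
    epochs and simulated raters; EEG preprocessing (zero-phase Butterworth
    band-pass, large Laplacian spatial filter, cue-locked epoching);
    cosine-similarity epoch morphology scoring, epoch averaging and automatic
    PN labelling; ICC(A,1) reliability statistics (two-way random effects,
    absolute agreement, single measures) with F-based confidence intervals and
    the standard error of measurement; and random-intercept linear and
    logistic association models with Tukey pairwise contrasts and
    matched-probability curves.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    lme4,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
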