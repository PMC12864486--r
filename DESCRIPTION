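Package: eegtraj
Title: Longitudinal Resting-State EEG Features for Predicting Progression
    from Amnestic MCI to Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for one-year progression prediction in
    amnestic mild cognitive impairment (aMCI) from repeated resting-state
    EEG measurements. Implements automated preprocessing (average reference,
    zero-phase FIR band-pass, 50 Hz notch, downsampling, segment selection),
    cross-sectional feature extraction (Welch band-power ratios, within-band
    spectral entropy, permutation entropy, sample entropy, the median
    distance from the centroid of a delay-embedded phase-space
    reconstruction, and alpha-band phase lag index), construction of six
    longitudinal trend descriptors per feature over three repeated
    measurements, fold-internal F-statistic feature selection, and repeated
    stratified cross-validated classification with eight classifiers. A
    synthetic cohort generator reproduces the group-by-time signal structure
    (progressive spectral slowing, falling complexity, falling alpha-band
    phase synchrony) so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
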