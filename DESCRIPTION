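Package: eegpath
Title: Multiscale Wavelet Features and Ensemble Learning for EEG
    Pathology Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies multichannel scalp EEG recordings as normal or
    pathological. Recordings are reduced to a standard 21-electrode 10-20
    montage, resampled to 250 Hz and cut into non-overlapping 5-second
    segments; each segment is decomposed with a 5-level sym6 discrete
    wavelet transform, six statistics (mean, mean absolute deviation,
    standard deviation, mean absolute value, skewness, kurtosis) are taken
    from the A5, D5, D4 and D3 sub-bands, and the per-segment feature
    vectors are z-scored. The segment axis is then collapsed by a
    multi-scale aggregation (standard deviation over the front half, rear
    half and all segments) and the patient age is appended, giving a
    compact per-recording feature vector that is classified with
    gradient-boosted trees or a random forest. Includes a seeded synthetic
    EEG cohort generator with class-dependent spectral structure, an
    EDF reader/writer, stratified cross-validation, ablation protocols
    (aggregation cases, age, brain-region channel subsets) and
    confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    signal,
    xgboost,
    ranger,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
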