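Package: eegaffect
Title: Time-Varying EEG Emotion Recognition with Leakage-Controlled Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for binary valence/arousal recognition
    from multichannel EEG annotated at twenty-second intervals. Provides a
    217-feature extractor (band log-powers via Welch spectra, hemispheric
    asymmetries, Hjorth parameters, detrended fluctuation analysis, Petrosian
    and Higuchi fractal dimensions, spectral and SVD entropy, Fisher
    information), greedy wrapper feature selection (sequential forward and
    backward), linear discriminant / linear-kernel SVM / convolutional-LSTM
    classifiers, four cross-validation frameworks with hard leakage guarantees
    (leave-one-person-out, leave-one-movie-out between and within subjects,
    leave-one-person-and-movie-out), fold-level F1 evaluation with
    Kolmogorov-Smirnov and Kruskal-Wallis comparison, and a synthetic cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    MASS,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
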