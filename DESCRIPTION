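Package: emgesture
Title: Riemannian Tangent-Space Classification of Surface EMG Hand Gestures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognizing hand and wrist gestures
    from multichannel surface electromyography (EMG). Implements powerline
    harmonic notch and band-pass Butterworth filtering, overlapping sliding
    window segmentation, spatial covariance matrices on the symmetric
    positive-definite manifold, affine-invariant Riemannian geometry
    (geodesic distance, Frechet mean, tangent-space features), short-training
    gesture classification with trial-wise cross-validation across thirteen
    classifier families, signal-to-noise-ratio evaluation, and a synthetic
    multichannel EMG generator with analytic ground-truth covariances for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    e1071,
    MASS,
    nnet,
    class,
    rpart,
    ranger,
    xgboost,
    nortest,
    jsonlite,
    optparse,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
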