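Package: alphasupp
Title: Visuocortical Alpha Suppression Analysis for Differential Conditioning EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for analysing conditioned suppression of
    occipital alpha-band (8-12 Hz) EEG activity in differential threat
    conditioning paradigms. Takes epoched multichannel EEG through a
    spherical-spline surface Laplacian (current source density) transform,
    variable-bandwidth complex Morlet wavelet power estimation, baseline
    percent-change normalization, frequentist and Bayesian 2x2 within-subject
    inference, per-sample tmax/tmin permutation testing with family-wise error
    control, and block-stability analysis. Includes a synthetic-data module
    that simulates epoched EEG with the paradigm's statistical structure
    (occipitally focal alpha oscillations, event-related desynchronization,
    1/f background noise, per-subject variability) so the entire pipeline can
    be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
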