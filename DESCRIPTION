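Package: fcanxgb
Title: Hybrid Feature-Attention Network and Gradient-Boosted Trees for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Four-quadrant valence-arousal emotion classification from
    multichannel EEG. Extracts differential-entropy and power-spectral-density
    features per channel and frequency band (theta, alpha, beta, gamma) with
    trial-wise baseline correction, processes them through a feature-attention
    network (parallel fully connected embedding branches, convolutional
    attention gating, feature fusion, and a tapped reduction network), and
    classifies the resulting deep features with gradient-boosted trees.
    Includes a synthetic EEG generator with class-dependent band-power
    structure, readers and writers for trial containers shaped like the
    common affective-EEG benchmarks, an ablation harness for fusion
    strategies, attention placement and tap depth, and full evaluation
    reporting (one-vs-rest metrics, confusion matrices, Cronbach's alpha).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
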