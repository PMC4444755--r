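Package: bubbleSTM
Title: Spike-Triggered Mask Analysis of Visual Driving Features from
    Bubble-Masked Natural Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies and characterizes the image regions ("driving
    features") that modulate the firing of visual cortical neurons, using
    natural images partially revealed through randomly positioned Gaussian
    bubble windows. Implements response-weighted spike-triggered mask
    estimation with a shuffle-based per-pixel significance test, spectral
    receptive field (orientation x spatial frequency) estimation from
    dynamic grating sequences, a quasi-linear amplitude-only Fourier filter
    model that predicts excitatory and suppressive driving features from
    the spectral receptive field, and a gaze-contingent analysis that
    quantifies translation invariance of driving features under fixational
    eye movements. A synthetic-neuron simulator (linear spectral channels,
    localized feature templates with tuned suppression, and a continuous
    retinotopic-to-head-centered position-coding parameter) generates
    complete surrogate recording sessions so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
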