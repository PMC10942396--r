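Package: anticiprf
Title: Anticipatory Spatial Attention Effects on Population Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for concurrent
    psychophysics-fMRI experiments on anticipatory covert spatial attention.
    Builds event-related pRF mapping designs (bar apertures, trial schedules,
    GLM design matrices), generates synthetic surface-vertex BOLD time series
    with known population receptive fields and known attentional modulation,
    estimates per-condition responses with an event-related GLM, fits
    isotropic 2D-Gaussian pRF models by coarse-to-fine search, and quantifies
    attentional effects: additive baseline shifts and their polar-angle
    tuning (difference-of-von-Mises fits), hemodynamic latency of attentional
    modulation (logistic fits and Bayes factors), attention-induced pRF
    center shifts with shuffled-label controls, and signal-detection
    behavioral sensitivity with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
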