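Package: pinchcoh
Title: Force Steadiness, Motor-Unit Firing and Intermuscular Coherence for Isometric Pinch Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trapezoidal isometric pinch contractions
    recorded with surface electromyography (EMG) and decomposed motor-unit
    spike trains. Provides target-referenced force-steadiness metrics with a
    steadiest-window search, motor-unit spike-train quality filtering, firing
    rate and recruitment-threshold estimation with a mixed-model group
    comparison, the full intermuscular-coherence chain (Hilbert-envelope
    preprocessing, segment-averaged spectra, pooled coherence, chi-squared
    difference-of-coherence tests, band summaries), shape-based (k-shape)
    clustering of EMG activity envelopes, and bootstrap group statistics with
    Cohen's d effect-size labels. A protocol-faithful motor-neuron-pool
    simulator generates ground-truthed synthetic cohorts (force, multi-channel
    EMG, spike trains, injectable common oscillatory drive) so every stage is
    testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    grDevices,
    graphics,
    signal,
    lme4,
    emmeans,
    cluster,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    boot,
    withr
Config/testthat/edition: 3
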