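Package: rvt
Title: Recurrent Convolutional Vision Models with Entropy-Threshold Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains, and analyses a family of recurrent convolutional
    neural networks with lateral (within-layer) connections and their
    parameter-matched feedforward controls. Networks emit a category readout
    at every time step; an entropy-threshold decision rule turns the readout
    sequence into anytime predictions with image-specific reaction times,
    tracing a speed-accuracy trade-off as the threshold varies. Includes
    closed-form parameter and floating-point-operation accounting for the
    architecture family, McNemar-based paired model comparison, a pipeline
    that fits entropy thresholds to subject-by-image reaction-time matrices
    by double leave-one-out cross-validation (with noise-ceiling and
    permutation statistics), principal-component analysis of learned lateral
    weight templates, and a synthetic image task plus synthetic subject
    generator so that every stage runs at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
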