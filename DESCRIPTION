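Package: kymoflux
Title: Kymograph-Based Quantification of Axonal Cargo Transport and
    Lysosomal Rupture Assays
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@posteo.net",
           role = c("aut", "cre"))
Description: Tools for quantifying axonal transport of vesicular cargo
    (lysosomes, mitochondria) from live-cell time-lapse microscopy:
    conversion of image stacks to calibrated kymographs, particle track
    extraction, segmentation of tracks into directed runs and pauses with
    diffusion-aware thresholds, and per-movie transport statistics (flux,
    velocity, run length, pause duration, directionality, stationary
    fraction, density). Also includes spot detection with two-channel
    puncta colocalization for lysosomal rupture assays, field-of-view
    intensity quantification with background-multiple thresholding, group
    comparison statistics (Welch/pooled t, one-way ANOVA with Tukey HSD),
    and a stochastic simulator of bidirectional cargo transport and puncta
    fields that provides ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
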