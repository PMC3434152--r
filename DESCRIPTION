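Package: whisknovelty
Title: Adaptive-Filter Novelty Detection for Whisker Sensory Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of internal-model novelty detection
    for active vibrissal (whisker) sensing. Provides a synthetic whisking
    plant (second-order linear reafferent dynamics with an optional bilinear
    motor-state cross term), Bernoulli-scheduled contact transients rendered
    through an impulse-response model, a least-mean-squares (LMS) tap-delay
    adaptive filter that predicts the self-generated (reafferent) component
    of the sensory signal from motor, sensory, or combined sensorimotor
    inputs, and a comparator whose output is a novelty signal dominated by
    external contact events. Includes ARX system identification of the plant
    from input-output records, signal-to-noise-ratio scoring of novelty
    outputs around contact times, and a seeded scenario grid comparing
    filter input wirings across stochastic/periodic whisking and
    linear/nonlinear plant dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Matrix,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
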