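Package: troutmove
Title: Habitat-Weighted Movement Bias of Brown Trout in River Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An eco-hydraulic toolkit that converts an upstream discharge
    scenario on a dendritic river network into per-reach hydraulics (Manning
    normal flow in rectangular channels), habitat suitability indices for
    adult and juvenile brown trout (Salmo trutta), and habitat-weighted
    movement biases and movement probabilities between adjacent reaches.
    Includes a Markov movement simulator built on those probabilities,
    nonlinear fitting of habitat suitability curves, and generators for
    synthetic river networks and suitability samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
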