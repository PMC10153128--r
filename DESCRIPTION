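Package: laminarodd
Title: Laminar Visual Oddball Electrophysiology Analysis with Ground-Truth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for laminar (16-channel linear probe) local field
    potential recordings collected during visual oddball paradigms in rodent
    primary visual cortex. Implements current source density estimation with
    layer-4 alignment and a four-layer partition, multiunit activity envelope
    extraction, Morlet wavelet induced power with global baseline correction,
    surrogate-corrected inter-electrode phase synchrony, and the associated
    statistics (windowed paired contrasts, layer-by-context repeated-measures
    ANOVA on time-frequency regions of interest, and cluster-mass permutation
    tests). Ships a forward simulator of laminar recordings with injected,
    parameterised deviance-detection and adaptation effects so that every
    analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    ggplot2,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
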