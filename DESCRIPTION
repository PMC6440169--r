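Package: emgonset
Title: EMG Movement-Onset Detection with Adaptive Gaussian Mixture Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the onset of voluntary movement from multichannel surface
    electromyography (sEMG). Time-domain features computed over sliding windows
    are modelled per feature by a two-component Gaussian mixture (rest vs
    movement) fitted by expectation-maximization; the rest/movement decision
    threshold is derived from the fitted densities and adapted sequentially
    during operation with an exponential forgetting factor, so the detector
    tracks drifting background noise. Single-muscle and multi-muscle
    majority-voting detectors are provided, together with an
    information-theoretic breakdown (linear, redundancy and synergy terms) for
    subject-independent feature and muscle selection, event-wise performance
    metrics (sensitivity, specificity, latency against kinematic and torque
    reference onsets), a protocol-faithful synthetic session generator with
    full ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
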