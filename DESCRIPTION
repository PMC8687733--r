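Package: wdrtherm
Title: Thermal Coding of Spinal Wide-Dynamic-Range Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spinal wide-dynamic-range (WDR) neuron
    responses to contact-thermode stimulation of the skin. Provides the
    stimulation-protocol families used with Peltier thermodes (fast single
    stimuli, slow ramps, 1 Hz iterative trains, response-curve steps), a
    calibrated one-dimensional heat-conduction model of the skin that predicts
    temperature at nociceptor depth and threshold-crossing latencies, a
    phenomenological inhomogeneous-Poisson spike-train generator with
    facilitation, adaptation and post-discharge, and the complete spike-train
    quantification pipeline: first-spike latency, baseline-subtracted windowed
    rates, slow-ramp activation thresholds, wind-up profiles with exponential
    decay fits, hot/cold response curves, peristimulus time histograms, and
    response-based neuron classification, together with the associated
    statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
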