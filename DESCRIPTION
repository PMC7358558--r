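Package: gsdsnn
Title: On-Chip Training Simulation for Spiking Neural Networks with Analog Synaptic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-aware simulator of supervised on-chip training for
    spiking neural networks built from analog synaptic devices. Models the
    gated-Schottky-diode conductance response to program/erase pulses
    (logarithmic LTP/LTD curves with a tunable non-linearity factor),
    differential-pair crossbar arrays with a parallel bias-selective update
    scheme, integrate-and-fire neurons driven by Poisson rate-coded inputs,
    and an approximated backpropagation rule that stores only two bits per
    neuron (a derivative bit and a last-time-step spike bit). Includes
    device non-ideality models (non-linearity, asymmetry, pulse-to-pulse and
    device-to-device variation, stuck-at-off devices), an off-chip
    ANN-to-SNN conversion baseline, sweep experiments, an MNIST IDX reader,
    and a deterministic synthetic classification task for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
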