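Package: lifmap
Title: Mapping and Validating Leaky Integrate-and-Fire Neurons on
    Fixed-Point Neuromorphic Hardware
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates leaky integrate-and-fire (LIF) point-neuron models
    expressed in physical units (ms, mV, pA, pF) into the quantized
    fixed-point parameterization of a neuromorphic compartment (12-bit
    decay constants, 23-bit state registers, 17-bit thresholds,
    mantissa/exponent bias encoding), and validates the translation.
    Includes an exact-integration reference simulator for the continuous
    model, a bit-faithful software emulator of the hardware update rule,
    stimulus generators (constant bias, frozen spike-train fixtures,
    seeded Poisson trains), RMSE/Pearson validation with plot-ready
    diagnostics, and scripted experiments: single-neuron validation,
    temporal- and voltage-precision sweeps, multi-class neuron ensembles,
    and random excitatory/inhibitory network scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
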