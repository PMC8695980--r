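Package: membcpnn
Title: Memristor-Based Emulation of the BCPNN Bayesian-Hebbian Learning Rule
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the mapping of the Bayesian Confidence Propagation
    Neural Network (BCPNN) synaptic learning rule onto voltage-controlled
    memristive devices. Provides an exact discrete-time reference
    implementation of the BCPNN trace cascade (Z, E, P traces, synaptic
    weight and unit bias), a VTEAM memristor model with a nonlinear
    dopant-drift window function, a closed-form calibration that converts
    trace smoothing constants into drive-voltage pulses, a behavioral
    emulation of the five-memristor sample-and-hold synapse architecture
    (scalable to hypercolumn arrays), and a harness that generates
    synthetic spike scenarios and scores the emulation against the
    reference with error and correlation metrics.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
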