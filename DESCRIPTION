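Package: rippletlab
Title: Analysis and Simulation of Ultrafast (~400 Hz) Cortical Ripplet Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing optogenetically evoked ultrafast (~400 Hz)
    local field potential oscillations ("ripplets") in thalamorecipient
    cortex and the intracellular activity that accompanies them. Provides a
    hierarchical synthetic sweep generator (LFP, current-clamp and
    voltage-clamp modalities under control and pharmacological conditions),
    LFP component decomposition and ripplet feature extraction, spike-burst
    timing statistics and fast-spiking/regular-spiking cell classification,
    the Jitter-Based Synchrony Index (JBSI) with analytic chance correction
    and a Monte-Carlo oracle, spike-phase assignment relative to LFP or
    EPSC-IPSC cycles, voltage-clamp event-onset detection, an event-driven
    simulator of the proposed feedforward excitation-inhibition ripplet
    circuit, and nonparametric permutation and sign tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
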