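Package: astromem
Title: Astrocyte-Modulated Short-Term Synaptic Memory Models for Visual
    Change Detection
Version: 0.1.0
Authors@R:
    person("Astromem", "Developers", email = "astromem@example.org",
           role = c("aut", "cre"))
Description: Mean-field models of short-term synaptic depression with
    astrocytic modulation of release probability (tripartite synapse),
    embedded as a dynamic input layer in small feedforward networks, and
    compared against depression-only and recurrent baselines on a
    simulated visual change-detection task. Includes the task simulator
    (flash/gray schedule, Go/Catch trials, constrained omissions), a small
    convolutional image encoder producing 64-dimensional feature banks, a
    synthetic feature-bank generator, training with d-prime-based early
    stopping, and behavioural metrics: the hit/false-alarm d-prime index,
    stimulus-transition response matrices, and a matrix asymmetry index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
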