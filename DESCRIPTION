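Package: ecapscs
Title: Evoked Compound Action Potential Analysis and Closed-Loop Spinal
    Cord Stimulation Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing evoked compound action potentials (ECAPs)
    recorded from multi-contact epidural leads during spinal cord
    stimulation, and for simulating ECAP-controlled closed-loop dosing.
    Includes a synthetic-data generator for multi-channel epidural
    recordings in freely behaving rats (triphasic ECAP waveforms, linear
    recruitment above threshold, distance attenuation, conduction delay,
    posture-driven gain fluctuations), triphasic P1/N1/P2 feature
    extraction, input-output recruitment-curve fitting with threshold
    extrapolation, conduction-velocity estimation from multi-contact
    latencies, pulse-on-pulse closed-loop amplitude control simulation,
    and von Frey / acetone behavioural hypersensitivity statistics with
    repeated-measures ANOVA and Bonferroni-corrected post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
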