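Package: stopmeg
Title: Stop/Change-Signal Behavior and MEG Source Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for stop-signal and change-of-plan
    experiments with simultaneous magnetoencephalography. Generates horse-race
    behavior under a dual-thread adaptive SOA staircase together with
    sensor-level recordings carrying known oscillatory source effects, and
    analyses them with the matching pipeline: trial classification and session
    screening, stop-signal reaction time estimation (average-difference,
    integration, and a Bayesian MCMC inhibition-function fit with reaction-time
    drift correction), LCMV beamformer source extraction, multitaper RMS
    time-frequency decomposition, a convolution GLM that disambiguates
    overlapping induced responses, and sign-flip permutation statistics with
    familywise error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite
Config/testthat/edition: 3
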