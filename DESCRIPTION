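Package: mazelfp
Title: Water-Maze LFP Analysis: Epoching, Artifact Scrubbing, Multitaper
    Spectra and Theta-Gamma Cross-Frequency Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for dual-site local field potential (LFP)
    recordings made during water-maze behaviour: task-phase epoch
    extraction (pre-maze baseline, in-maze swim, platform), automated
    sliding-window burst-artifact scrubbing with a recovered-signal
    metric, RMS-normalised multitaper power spectral density and
    magnitude-squared coherence with theta-band peak extraction,
    normalised-entropy theta-gamma phase-amplitude modulation index
    with comodulogram scanning and circular-shift surrogate z-scores,
    fixed-effects ANOVA group statistics with Bonferroni follow-ups,
    and double-H maze trial scoring. Includes a synthetic-LFP session
    generator with controllable coupling strength, between-channel
    theta coherence and ground-truth artifact bursts for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
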