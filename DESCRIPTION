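Package: bcilearn
Title: Closed-Loop Imagined-Speech BCI Simulation and Learning-Dynamics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses multi-day closed-loop brain-computer
    interface (BCI) training based on two-class syllable imagery. Provides a
    synthetic EEG/EMG session generator with class-dependent spectral
    signatures and per-participant learning trajectories, offline
    preprocessing (zero-phase band-pass filtering, epoching, common-average
    re-referencing, automated artifact rejection with neighbour
    interpolation), power-spectral-density feature extraction over sliding
    windows, random-forest decoder calibration with trial-stratified
    cross-validation, a simulated online feedback loop with battery-style
    feedback (continuous or discontinuous display), learning-dynamics
    indices (learning slopes, planned-contrast mixed models, feature-weight
    summaries, a global feature-change index), Morlet time-frequency
    analysis with sensor-space cluster-based permutation statistics, and a
    mental-chronometry analysis built around a deviation-from-isochrony
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    ranger,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
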