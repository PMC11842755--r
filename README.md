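# bcilearn

Simulation and analysis of closed-loop **imagined-speech brain–computer
interface (BCI) training**.

In the paradigm this package models, a participant imagines pronouncing one
of two syllables (/fɔ/ vs /gi/) while 64-channel EEG is recorded at 512 Hz.
A random-forest classifier, calibrated on an offline session, decodes the
imagined syllable in real time from power-spectral-density (PSD) features
— one feature per (channel, frequency) pair, 61 scalp channels × 35
frequency bins (2–70 Hz in 2 Hz steps) = 2135 features — and drives a
battery-style visual feedback: whenever the decoded probability of the cued
syllable increases, the battery fills a little; when it does not, it
empties a little. Training runs over 5 days, and the scientific questions
are about *learning*: does online control improve, how do the classifier's
feature weights reorganize, how does band-limited EEG power evolve, and is
any of it reflected in mental chronometry (the ability to imagine speech
with realistic timing)?

Because human recordings cannot ship with a package, `bcilearn` includes a
first-class **synthetic session generator**: 1/f background activity from
spatially smooth sources, a shared alpha rhythm, and class-dependent
band-limited components at configurable signature loci whose strength
follows a per-participant learning trajectory. Every analysis stage can
therefore be exercised, calibrated and validated at desk scale.

## What the package computes

| Stage | Functions |
|---|---|
| Montage & synthetic data | `make_montage`, `learner_profile`, `simulate_session`, `simulate_epoch_set`, `simulate_cohort`, `simulate_chronometry` |
| Preprocessing | `bandpass` (zero-phase Butterworth 1–70 Hz), `epoch_trials` (12 s epochs, −4…+8 s), `rereference_common_average`, `reject_and_interpolate` |
| Features | `feature_config` (500 ms windows, 20 ms hop), `build_feature_index`, `extract_features`, `restrict_to_emg` |
| Decoder | `calibrate` (random forest, trial-stratified 8-fold CV, weights in %), `predict_proba` |
| Closed loop | `run_online_trial`, `trial_performance`, `run_online_session` |
| Learning dynamics | `learning_slope`, `planned_contrast_lmm` (day contrast −2…+2), `topk_weight_sum`, `frequency_profile`, `band_topography`, `global_change_index`, `trend_permutation_by_feature`, `correlate` |
| Spectral dynamics | `morlet_tfr`, `baseline_normalize` (% change vs −3…−2 s), `band_average`, `cluster_test_baseline`, `cluster_test_trend`, `brain_behavior_interaction` |
| Chronometry | `deviation_from_isochrony` (`abs(1 − imagine/speak)`), `isochrony_table`, `chronometry_trends` |

Key quantitative definitions:

- **BCI-control performance** of a trial: the percentage of decoder
  outputs matching the cued syllable over the ≤ 5 s control period.
- **Planned contrast**: per-day weights (−2, −1, 0, 1, 2) testing a linear
  trend over the 5 training days inside a linear mixed model with a random
  intercept per participant.
- **Global feature-change index**: the mean over the four consecutive-day
  Euclidean distances between full weight maps,
  `dist(DayN+1, DayN) = sqrt(Σ_i (w_i(DayN+1) − w_i(DayN))²)`.
- **Deviation from isochrony**: `abs(1 − Imagine/Speak)` on day-mean
  repetition durations; 0 means temporally faithful imagery.

## Worked example

Calibrate a decoder on a simulated day-5 offline session and run the
simulated online session through the feedback loop (16-channel montage for
speed; the default is the 64-channel system):

```r
library(bcilearn)

montage <- make_montage(16)
profile <- learner_profile(participant_id = "P01")   # improving learner

ep_cal   <- simulate_epoch_set(profile, day = 5, "offline", montage,
                               n_per_class = 8, seed = 1)
features <- extract_features(ep_cal, feature_config(hop = 0.25))
decoder  <- calibrate(features, k = 8, seed = 1)
decoder
#> <bci_decoder> 455 features, 500 trees; CV accuracy 92.1%

ep_onl  <- simulate_epoch_set(profile, day = 5, "online", montage,
                              n_per_class = 8, seed = 2)
session <- run_online_session(decoder, ep_onl, feature_config(hop = 0.1))
round(session$mean_performance, 1)
#> [1] 91.6
head(session$trials[, c("trial", "class", "performance", "outcome")], 3)
#>   trial class performance outcome
#> 1     1    gi    91.30435 timeout
#> 2     2    fo    89.13043 timeout
#> 3     3    fo    95.65217 timeout

round(topk_weight_sum(decoder, k = 100), 1)
#> [1] 63
```

The CV accuracy (92.1%) is the held-out window-level accuracy of the
trial-stratified 8-fold cross-validation; the mean online performance
(91.6%) is the average percentage of decoder outputs matching the cue
across the 16 online trials; the top-100 weight sum (63%) says that under
a strong planted effect the forest concentrates almost two thirds of its
total importance on ~a fifth of the feature space — the quantity whose
growth across days indexes feature-space consolidation during learning.

For a full 5-day cohort study (performance trends, learning slopes,
weight-map dynamics) see `run_cohort_study()` /
`summarize_cohort_learning()` and the methods vignette
(`vignettes/bcilearn-methods.Rmd`).

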