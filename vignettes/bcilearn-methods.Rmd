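---
title: "Methods: simulating and analysing imagined-speech BCI training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing imagined-speech BCI training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcilearn)
```

# The experimental model

`bcilearn` models a two-class imagined-speech BCI protocol: on each trial
the participant sees a trial number (1 s), a fixation cross (2 s) and a
written syllable cue (2 s), then imagines pronouncing the cued syllable
(/fɔ/ or /gi/) for up to 5 s while a battery on the screen provides
feedback, followed by a 2 s hold and a rest period. A session comprises 40
trials per syllable in 4 blocks (10 per syllable per block, order
randomized within block). Offline sessions (no veridical feedback)
calibrate the decoder; online sessions stream the EEG through it in real
time. Training spans 5 days.

The recording system is modelled as 64 EEG channels at 512 Hz — 61 scalp
channels on an idealized extended 10-20 sphere plus 3 mastoid-region
channels — together with a reference site and two perioral EMG electrodes.
Feature extraction excludes the mastoid-region channels and the reference,
leaving 61 channels. The published channel counts are ambiguous about
whether the reference was one of the 64 recorded channels; this montage
places it outside the 64, which makes the exclusion rule yield exactly 61
by construction. Smaller caps (8, 16, 32) with the same structure are
provided for desk-scale work.

# The synthetic generator

Real recordings cannot be redistributed, so the generator is a first-class,
tested component. Scalp signal is the sum of:

* **1/f background** from `K` virtual sources (unit-sphere positions on the
  scalp) mixed to channels by a Gaussian kernel of great-circle distance —
  this gives the background its spatial smoothness, which matters for
  common-average referencing, neighbour interpolation and cluster tests;
* a **shared 10 Hz alpha rhythm** with posterior-weighted amplitude and a
  random phase per session;
* **per-channel sensor noise** (white, 2 µV);
* **class-dependent signature components**: band-limited Gaussian noise
  added during imagery windows only, at two loci — left-central channels at
  8–16 Hz and bilateral temporal channels at 52–66 Hz, with opposite class
  signs so neither class is globally stronger. The amplitude of a component
  is `a0 * exp(±d/2)`, where the sign depends on the trial's class and `d`
  is the participant's discriminability that day:
  `d(day) = max(0, base + rate × (day − 1))`.

EMG channels carry 20–150 Hz broadband activity plus a small
class-dependent 30–70 Hz component scaled by the profile's `emg_leakage`,
so that decoding from EMG alone is above chance but far weaker than from
EEG — a model of subthreshold articulator leakage as a decoding confound.

**Parameter choices.** The defaults (`base_discriminability = 0.3`,
`learning_rate = 0.15`) were fixed once by simulation so that a default
learner is realistic: decoding is modest on day 1 and clearly above the
65% usability threshold by day 5, without saturating online performance at
100% (which would destroy the variance that the learning-dynamics analyses
feed on). Cohorts (`simulate_cohort`) default to 15 participants of whom
11 have a positive planted learning rate, mirroring the typical fraction
of responders in multi-day BCI training studies. Chronometry durations are
log-normal (positive, right-skewed, as timed-performance data are), with
per-modality means near 3 s and a per-day drift.

**What the generator does *not* model:** eye-blink and movement artifacts,
line noise, electrode drift, non-stationary background, volume-conduction
head modelling, or strategy changes within a day. Passing tests on this
generator therefore validate the *analysis machinery* (calibration,
inference, recovery of planted effects), not the difficulty of real EEG.

# Preprocessing

Offline cleaning follows the standard sequence: zero-phase Butterworth
band-pass 1–70 Hz (order 4 one-way, effective order 8), epoching into 12 s
windows from −4 to +8 s around imagery onset (6144 samples), common-average
re-referencing over scalp channels, artifact handling, and interpolation of
bad channels.

Two deliberate substitutions:

* The band-pass is applied by default in the frequency domain using the
  Butterworth's squared magnitude response — the exact steady-state
  response of forward–backward filtering — in one FFT pass over all
  channels; `method = "filtfilt"` runs the time-domain equivalent. The two
  agree to ~1e-6 away from the recording edges (tested).
* Inspection-guided artifact removal is replaced by a deterministic rule:
  robust z-scores (median/MAD) of per-epoch and per-channel log
  peak-to-peak amplitude, threshold 5; flagged epochs are dropped, flagged
  channels interpolated by inverse-great-circle-distance weighting over
  montage neighbours. An automated rule is reproducible and testable,
  which inspection is not; spherical-spline interpolation was judged
  unnecessary at these channel counts.

Channels are montage neighbours below a per-cap great-circle radius chosen
so the median scalp channel of the 64-channel system has 4–8 neighbours
and no cap has isolated channels.

# Features

A 500 ms window at 512 Hz has a natural 2 Hz periodogram spacing, and the
35-bin grid {2, 4, …, 70} Hz is the unique grid reconciling a 1–70 Hz
range, 2 Hz resolution and 35 bins per channel; with 61 channels that
yields the canonical 2135-dimensional feature space, ordered channel-major
with frequency ascending. Windows slide in 20 ms steps (480 ms overlap),
i.e. a 50 Hz decoder update rate — the reading consistent with continuous
feedback (the alternative reading, 480 ms steps, would allow only ~10
updates per trial). Each window gets a Hann taper and a single-window
periodogram (no sub-window averaging), log10-transformed with a 1e-12
µV²/Hz floor for variance stabilization; the floor makes the zero-signal
case well-defined. Window onsets are laid out on the time axis and rounded
to samples, so the window count per segment is exact (226 windows over
5 s) even though 20 ms is not an integer number of samples at 512 Hz.

# Decoder

A probability random forest (`ranger`; 500 trees, sqrt-features per split,
unrestricted depth, fixed seed) on the log-PSD features. Feature weights
are impurity importances normalized to sum to 100%, arranged as a
channel × frequency map. Cross-validation is 8-fold with **folds
stratified at the trial level**: all windows of a trial share a fold,
otherwise the 480 ms window overlap leaks across folds and inflates
accuracy. Fold assignment cycles a global counter across classes so folds
stay class-balanced whenever trial counts allow. CV accuracy is the mean
held-out window-level accuracy. The EMG-restricted mode simply restricts
the feature matrix to the 2 EMG channels × 35 bins = 70 columns and reuses
the identical calibration path.

# The closed loop

At each update the change in cued-class probability,
`dp = p(t) − p(t − hop)`, moves the battery by `delta × sign(dp)`, clipped
to [0, 1]; the first step compares against the uninformative prior 0.5,
and `sign(0) = 0` (an exactly constant probability freezes the battery).
`delta` defaults to 1/250 so a uniformly favourable 5 s trial at 20 ms
updates fills the battery exactly at the timeout. Continuous mode displays
the battery; discontinuous mode displays its running maximum (a ratcheted
display that only ever shows increments — an approximation of
schedule-based discontinuous feedback, whose exact schedule is not
modelled). Both modes share the identical internal battery and identical
trial performance; only the display differs, making the performance metric
feedback-independent by construction. Trial performance is the percentage
of update steps whose probability argmax matches the cue, with exact ties
(p = 0.5) counted as non-matching.

# Learning dynamics

* Per-participant **learning slope**: OLS slope of per-day mean
  performance on day 1…5.
* **Planned-contrast mixed model**: day coded with centered, equally
  spaced weights (−2, −1, 0, 1, 2), entered as a fixed effect with a
  random intercept per participant. The Satterthwaite F test (`lmerTest`)
  is reported together with a likelihood-ratio p value against the
  intercept-only model; type-I calibration of the test is verified by
  simulation in the suite.
* **Top-k weight sum** (k = 200 by default, configurable; at that rank
  the cumulative weight typically exceeds half the total, which is what
  makes the statistic informative): ranks are decreasing with
  deterministic tie-breaking in channel-major order so sums are exactly
  reproducible.
* **Global change index**: mean of the 4 consecutive-day Euclidean
  distances between full weight maps — symmetric, non-negative, zero iff
  all maps are equal, linear under global rescaling (all tested against
  brute-force oracles).
* **Per-key permutation trend test**: per participant, the
  contrast-weighted sum over days; a one-sample t across participants per
  key; the null reshuffles day labels within participants, with the same
  reshuffle applied to every key of a permutation so the map-level null
  preserves cross-key dependence. Two-tailed p values are floored at
  1/(n_perm + 1).

# Spectral dynamics

Morlet wavelets decompose epochs into time-frequency power, with cycles
increasing linearly from 3 at 4 Hz to 7 at 70 Hz (clamped) — a standard
compromise between temporal resolution at low and spectral resolution at
high frequencies; wavelets longer than the epoch raise an error naming
the offending frequency. Power is baseline-normalized per trial, channel
and frequency as percent change from the −3…−2 s fixation window, then
averaged within the canonical bands (theta 4–7, alpha 8–13, beta 14–26,
low-gamma 27–40, high-gamma 41–70 Hz) over the 5 s control window.

Sensor-space inference uses cluster-based permutation tests: per-channel
t statistics, a two-tailed cluster-forming threshold at α = 0.05 with
participant-level degrees of freedom, adjacency-connected clusters formed
separately per sign, and the maximal cluster statistic under the
permutation null (within-participant sign flips for the baseline
contrast; within-participant day reshuffles for the trend). The cluster
statistic is **size** (channel count) by default, with summed-|t| mass as
an option — the choice is genuinely open in the literature; size is the
default here because the upstream description compares cluster sizes, and
mass is preferable when single-channel effects are expected. An exact
mode enumerates all 2^n sign flips for small cohorts, enabling
equality-level validation against a brute-force oracle.

The brain–behaviour interaction (does the power–performance coupling
strengthen with training?) models per-participant-per-day performance on
channel power, the contrast-coded day and their interaction. The
statistic uses OLS with participant dummy intercepts rather than
refitting a mixed model inside every permutation: with balanced panels
the interaction estimate coincides with the mixed-model fixed-effect
estimate, and inference comes from the permutation distribution (day
labels reshuffled within participants), so the approximation does not
change the test's validity — it changes its cost by two orders of
magnitude.

# Chronometry

The deviation-from-isochrony index `abs(1 − Imagine/Speak)` is computed
from day-mean durations per modality, pooling the two syllables (the
pooled reading of "average duration"; per-syllable indices can be formed
by filtering the input table). The index is scale-invariant and zero iff
the two modalities take equal time. Trends use the same planned-contrast
machinery, with modality and (when present) feedback group as fixed
factors; incomplete participant × day × modality cells are rejected with
a diagnostic naming the first missing cell rather than silently dropped.

# Numerical and scale choices

* All generators and permutation engines are pure functions of their
  arguments and a seed; sub-seeds are derived by integer mixing and stay
  below 2^31.
* `simulate_epoch_set` generates only the −1…+6 s neighbourhood of each
  trial (identical generative structure, inter-trial intervals omitted);
  it backs the cohort driver `run_cohort_study`, whose default problem
  size — 8-channel cap, 4 trials per class per session, coarse 250 ms
  calibration hop, 150 trees — was chosen once as the smallest
  configuration at which the planted learning structure is still
  recovered cleanly (trend significance, slope–rate correlation ≈ 0.95,
  learner/non-learner separation of the global change index).
* The chance-level control and the cluster-test false-positive rate are
  recomputed from scratch by `scripts/acceptance.R` (20 null 80-trial
  sessions; 200 null 15-participant datasets at 500 permutations); the
  test suite runs reduced but structurally identical versions of the same
  checks.

# Known limitations

* The generator's stationary, artifact-free background makes preprocessing
  easier than on real data; rejection thresholds validated here should be
  re-examined on real recordings.
* The discontinuous-feedback mode is a ratchet model, not a reconstruction
  of any specific experimental schedule, and the paced (metronome)
  chronometry variant is not modelled.
* Online simulation is not real-time: windows are streamed causally but
  acquisition latency is not modelled.
* With the smallest caps, some trial counts admit below-chance
  cross-validation bias (unbalanced training folds when a class has fewer
  trials than folds); the calibration analyses therefore use balanced
  configurations of at least 16 trials per class.
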