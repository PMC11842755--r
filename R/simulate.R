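# Synthetic session generator. Emulates a two-class syllable-imagery BCI
# protocol: 1/f background activity from spatially smooth sources, a shared
# 10 Hz rhythm, and class-dependent band-limited components at the
# participant's signature loci during imagery windows, scaled by that day's
# discriminability. EMG channels carry broadband muscle-like activity plus a
# small class-dependent "subthreshold leakage" component.

#' Default class-signature loci
#'
#' The two imagery classes differ in band-limited power at left-central
#' sites in the mu/low-beta range (8-16 Hz) and at bilateral temporal sites
#' in the high-gamma range (52-66 Hz); the sign is opposite at the two loci
#' so neither class is globally "stronger".
#'
#' @return List of loci, each with `channels` (group name), `band` (Hz) and
#'   `sign` (+1/-1).
#' @export
default_signature <- function() {
  list(
    list(channels = "left_central", band = c(8, 16), sign = +1),
    list(channels = "temporal", band = c(52, 66), sign = -1)
  )
}

#' Construct a simulated learner profile
#'
#' A profile bundles the participant-level parameters of the generator: the
#' baseline class discriminability, its per-day change (the planted learning
#' rate), the spectral signature loci, EMG leakage, and mental-chronometry
#' parameters. Discriminability on day d is `max(0, base + rate * (d - 1))`
#' and multiplies the log-amplitude contrast between the two classes at the
#' signature loci.
#'
#' @param participant_id Identifier string.
#' @param base_discriminability Dimensionless effect amplitude on day 1
#'   (>= 0).
#' @param learning_rate Additive per-day change in discriminability.
#' @param signature List of signature loci (see [default_signature()]).
#' @param emg_leakage Effect amplitude of class-dependent EMG modulation
#'   (>= 0).
#' @param chronometry_params List with `imagine_mean`, `speak_mean` (s),
#'   `sdlog` (log-normal dispersion), `drift_imagine`, `drift_speak`
#'   (s/day).
#' @return Object of class `learner_profile`.
#' @export
learner_profile <- function(participant_id = "P01",
                            base_discriminability = 0.3,
                            learning_rate = 0.15,
                            signature = default_signature(),
                            emg_leakage = 0.5,
                            chronometry_params = list(
                              imagine_mean = 3.4, speak_mean = 3.0,
                              sdlog = 0.15,
                              drift_imagine = -0.05, drift_speak = -0.05)) {
  pars <- c(base_discriminability, learning_rate, emg_leakage,
            unlist(chronometry_params))
  if (!all(is.finite(pars))) stop_bci("non-finite profile parameters")
  if (base_discriminability < 0 || emg_leakage < 0) {
    stop_bci("effect amplitudes must be >= 0")
  }
  structure(list(participant_id = participant_id,
                 base_discriminability = base_discriminability,
                 learning_rate = learning_rate,
                 signature = signature,
                 emg_leakage = emg_leakage,
                 chronometry_params = chronometry_params),
            class = "learner_profile")
}

#' Day-specific discriminability of a profile
#' @param profile A `learner_profile`.
#' @param day Training day (1-5).
#' @return Non-negative scalar.
#' @export
discriminability <- function(profile, day) {
  max(0, profile$base_discriminability + profile$learning_rate * (day - 1))
}

# 1/f (power ~ 1/f) noise, one column per independent source, via spectral
# shaping of white Gaussian noise. `sd` is the target standard deviation.
pink_noise <- function(n, n_src, fs, sd = 1) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  amp <- 1 / sqrt(f)
  re <- matrix(stats::rnorm(nf * n_src), nf, n_src)
  im <- matrix(stats::rnorm(nf * n_src), nf, n_src)
  spec <- complex(real = amp * re, imaginary = amp * im)
  dim(spec) <- c(nf, n_src)
  full <- matrix(0 + 0i, n, n_src)
  full[2:(nf + 1), ] <- spec
  full[n:(n - nf + 2), ] <- Conj(spec[1:(nf - 1), , drop = FALSE])
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  x <- scale(x, center = TRUE, scale = TRUE)
  x[] <- x * sd
  x
}

# Band-limited Gaussian noise with raised-cosine onset/offset ramps,
# generated by FFT masking; k independent unit-variance columns.
band_noise <- function(n, fs, band, k = 1, ramp = 0.1) {
  w <- matrix(stats::rnorm(n * k), n, k)
  spec <- stats::mvfft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # fold to two-sided frequencies
  mask <- f >= band[1] & f <= band[2]
  x <- Re(stats::mvfft(spec * mask, inverse = TRUE)) / n
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  x <- sweep(x, 2, s, "/")
  nr <- round(ramp * fs)
  if (nr > 0 && 2 * nr < n) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[1:nr, ] <- x[1:nr, , drop = FALSE] * r
    x[(n - nr + 1):n, ] <- x[(n - nr + 1):n, , drop = FALSE] * rev(r)
  }
  x
}

# Smooth source-to-channel mixing: K virtual sources at a fixed subset of
# scalp sites, Gaussian kernel of great-circle distance. Gives the
# background its spatial correlation (so neighbour interpolation and
# common-average referencing behave as they do on real recordings).
mixing_matrix <- function(montage, sigma = 0.9) {
  eeg <- montage_channels(montage, "eeg")
  pos <- montage$positions[eeg, , drop = FALSE]
  sc <- montage_channels(montage, "scalp")
  k <- max(4L, min(10L, length(sc) %/% 5L))
  src_idx <- round(seq(1, length(sc), length.out = k))
  src_pos <- montage$positions[sc[src_idx], , drop = FALSE]
  cosang <- pmin(pmax(tcrossprod(pos, src_pos), -1), 1)
  ang <- acos(cosang)
  a <- exp(-(ang / sigma)^2)
  a / rowSums(a)
}

#' Build the trial schedule of one session
#'
#' Each trial consists of a trial-number display (1 s), a fixation cross
#' (2 s), a written syllable cue (2 s), 5 s of imagery, a 2 s hold period
#' and a rest period. Trials are arranged in 4 blocks with an equal number
#' of trials per class per block, class order randomized within block.
#'
#' @param n_per_class Trials per class (default 40; must be divisible by 4).
#' @param rest_dur Rest duration in seconds (default 5).
#' @param seed Integer seed for the within-block class order.
#' @return Data frame of class `trial_schedule` with per-trial phase onsets
#'   in seconds (`t_start`, `t_fixation`, `t_cue`, `t_imagery`),
#'   `imagery_dur`, `rest_dur`, `class` and `block`.
#' @export
make_schedule <- function(n_per_class = 40, rest_dur = 5, seed = 1L) {
  if (n_per_class %% 4 != 0) stop_bci("n_per_class must be divisible by 4")
  per_block <- n_per_class %/% 4L
  cls <- with_seed(mix_seed(seed, 11L), {
    unlist(lapply(1:4, function(b) sample(rep(c("fo", "gi"), per_block))))
  })
  n <- length(cls)
  trial_len <- 1 + 2 + 2 + 5 + 2 + rest_dur
  t0 <- (seq_len(n) - 1) * trial_len
  out <- data.frame(
    trial = seq_len(n),
    class = cls,
    block = rep(1:4, each = 2 * per_block),
    t_start = t0,
    t_fixation = t0 + 1,
    t_cue = t0 + 3,
    t_imagery = t0 + 5,
    imagery_dur = 5,
    rest_dur = rest_dur,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trial_schedule", "data.frame")
  out
}

# Core signal synthesis shared by simulate_session() and
# simulate_epoch_set(): smooth-source 1/f background, shared
# posterior-weighted alpha, sensor noise, class-dependent signature
# components during the imagery windows, EMG broadband + leakage.
gen_session_data <- function(montage, profile, d, cls, imagery_onsets, n,
                             fs, sseed) {
  labels <- montage$labels
  nch <- length(labels)
  groups <- signature_channel_groups(montage)
  with_seed(sseed, {
    eeg <- montage_channels(montage, "eeg")
    a <- mixing_matrix(montage)
    src <- pink_noise(n, ncol(a), fs, sd = 10)
    x <- matrix(0, nch, n, dimnames = list(labels, NULL))
    x[eeg, ] <- a %*% t(src)
    # shared posterior-weighted alpha rhythm
    tt <- seq_len(n) / fs
    alpha_amp <- 4 * (1 + stats::rnorm(1, 0, 0.1))
    alpha <- alpha_amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
    wpost <- clamp01(0.5 - montage$positions[eeg, "y"] / 2)
    x[eeg, ] <- x[eeg, ] + outer(wpost, alpha)
    # per-channel sensor noise
    x[eeg, ] <- x[eeg, ] + 2 * matrix(stats::rnorm(length(eeg) * n),
                                      length(eeg), n)
    # class-dependent signature components during imagery (batched FFT
    # noise: one column per trial x channel)
    nimg <- round(5 * fs)
    ntr <- length(cls)
    cls_sign <- ifelse(cls == "fo", 1, -1)
    onsets <- round(imagery_onsets * fs)
    for (locus in profile$signature) {
      chans <- groups[[locus$channels]]
      if (length(chans) == 0) next
      amp <- 1.5 * exp(cls_sign * locus$sign * d / 2)  # per trial
      nz <- band_noise(nimg, fs, locus$band, k = ntr * length(chans))
      for (ti in seq_len(ntr)) {
        idx <- onsets[ti] + seq_len(nimg)
        cols <- (ti - 1) * length(chans) + seq_along(chans)
        x[chans, idx] <- x[chans, idx] +
          amp[ti] * t(nz[, cols, drop = FALSE])
      }
    }
    # EMG: broadband muscle-like activity + subthreshold class leakage
    emg <- montage_channels(montage, "emg")
    x[emg, ] <- 20 * t(band_noise(n, fs, c(20, 150), k = length(emg),
                                  ramp = 0))
    amp_emg <- 6 * exp(cls_sign * profile$emg_leakage / 2)
    nz <- band_noise(nimg, fs, c(30, 70), k = ntr * length(emg))
    for (ti in seq_len(ntr)) {
      idx <- onsets[ti] + seq_len(nimg)
      cols <- (ti - 1) * length(emg) + seq_along(emg)
      x[emg, idx] <- x[emg, idx] + amp_emg[ti] * t(nz[, cols, drop = FALSE])
    }
    x
  })
}

#' Simulate one recording session
#'
#' Generates a continuous multichannel EEG/EMG recording (microvolt scale,
#' 512 Hz) plus its trial schedule. The scalp signal is a sum of spatially
#' smooth 1/f background sources, a shared 10 Hz rhythm, channel noise, and
#' class-dependent band-limited components at the profile's signature loci
#' that are present only during imagery windows; the class contrast is an
#' amplitude modulation `exp(+/- d/2)` where `d` is that day's
#' discriminability. EMG channels carry 20-150 Hz broadband activity plus a
#' class-dependent 30-70 Hz leakage component scaled by `emg_leakage`.
#' Output is bit-reproducible from `(profile, day, session, seed)`.
#'
#' @param profile A [learner_profile()].
#' @param day Training day, 1-5.
#' @param session `"offline"` (calibration) or `"online"` (feedback).
#' @param montage A [make_montage()] result.
#' @param n_per_class Trials per class (default 40).
#' @param rest_dur Rest duration in seconds (default 5).
#' @param seed Integer seed.
#' @return List with `recording` (class `bci_recording`: `data` channels x
#'   samples, `fs`, `montage`, `events`) and `schedule`.
#' @export
simulate_session <- function(profile, day, session = c("offline", "online"),
                             montage = make_montage(64),
                             n_per_class = 40, rest_dur = 5, seed = 1L) {
  session <- match.arg(session)
  if (!day %in% 1:5) stop_bci("day must be in 1..5")
  stopifnot(inherits(profile, "learner_profile"))
  fs <- 512
  sched <- make_schedule(n_per_class, rest_dur,
                         seed = mix_seed(seed, day, session == "online"))
  n <- round((max(sched$t_start) + 12 + rest_dur) * fs)
  d <- discriminability(profile, day)
  sseed <- mix_seed(seed, day * 2 + (session == "online"), 977L)
  data <- gen_session_data(montage, profile, d, sched$class,
                           sched$t_imagery, n, fs, sseed)
  check_finite(data, "simulated recording")
  events <- data.frame(sample = round(sched$t_imagery * fs) + 1L,
                       marker = paste0("imagery_", sched$class),
                       stringsAsFactors = FALSE)
  rec <- structure(list(data = data, fs = fs, montage = montage,
                        events = events,
                        meta = list(participant = profile$participant_id,
                                    day = day, session = session,
                                    seed = seed)),
                   class = "bci_recording")
  list(recording = rec, schedule = sched)
}

#' @export
print.bci_recording <- function(x, ...) {
  cat(sprintf("<bci_recording> %d channels x %d samples @ %d Hz (%s, day %s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              x$meta$session %||% "?", x$meta$day %||% "?"))
  invisible(x)
}

#' Simulate an epoched session directly
#'
#' Desk-scale variant of [simulate_session()]: generates only the
#' `[tmin, tmax]` window around each trial's imagery onset (trials packed
#' back to back), applies the zero-phase band-pass to the packed stream,
#' and returns the epoch set directly. The per-trial signal has the same
#' generative structure as the continuous session (background sources,
#' alpha, sensor noise, class-dependent signature components, EMG); only
#' the inter-trial intervals are omitted, which no epoch-based analysis
#' consumes.
#'
#' @inheritParams simulate_session
#' @param tmin,tmax Epoch window in seconds around imagery onset
#'   (`tmax >= 5` so the imagery period is fully contained).
#' @param filter Apply the default 1-70 Hz zero-phase band-pass
#'   (default TRUE).
#' @return An `epoch_set`.
#' @export
simulate_epoch_set <- function(profile, day, session = c("offline", "online"),
                               montage = make_montage(16),
                               n_per_class = 8, tmin = -1, tmax = 6,
                               filter = TRUE, seed = 1L) {
  session <- match.arg(session)
  if (!day %in% 1:5) stop_bci("day must be in 1..5")
  if (tmax < 5) stop_bci("tmax must be >= 5 to contain the imagery period")
  fs <- 512
  sched <- make_schedule(n_per_class, rest_dur = 1,
                         seed = mix_seed(seed, day, session == "online"))
  span <- tmax - tmin
  onsets <- (seq_len(nrow(sched)) - 1) * span - tmin
  n <- round(nrow(sched) * span * fs)
  d <- discriminability(profile, day)
  sseed <- mix_seed(seed, day * 2 + (session == "online"), 977L)
  x <- gen_session_data(montage, profile, d, sched$class, onsets, n, fs,
                        sseed)
  rec <- structure(list(data = x, fs = fs, montage = montage,
                        events = data.frame(sample = integer(0),
                                            marker = character(0)),
                        meta = list(participant = profile$participant_id,
                                    day = day, session = session,
                                    seed = seed)),
                   class = "bci_recording")
  if (filter) rec <- bandpass(rec)
  packed <- sched
  packed$t_imagery <- onsets
  epoch_trials(rec, packed, tmin = tmin, tmax = tmax)
}

#' Simulate a training cohort
#'
#' Draws per-participant learner profiles reproducibly from a seed:
#' `n_learners` participants receive a positive planted learning rate, the
#' remainder a non-positive one. The default shape (15 participants, 11
#' improving) mirrors the study design the generator emulates. Sessions for
#' any participant/day are materialized on demand via [simulate_session()]
#' using the per-participant seeds stored in the profiles.
#'
#' @param n_participants Cohort size (> 0).
#' @param n_learners Number of participants with positive learning rate
#'   (<= n_participants).
#' @param seed Integer seed.
#' @return Object of class `bci_cohort`: list of profiles with a
#'   `session_seed` attribute each.
#' @export
simulate_cohort <- function(n_participants = 15, n_learners = 11, seed = 7L) {
  if (n_participants < 1) stop_bci("n_participants must be >= 1")
  if (n_learners > n_participants) {
    stop_bci("n_learners must be <= n_participants")
  }
  profiles <- with_seed(mix_seed(seed, 313L), {
    lapply(seq_len(n_participants), function(i) {
      is_learner <- i <= n_learners
      rate <- if (is_learner) stats::runif(1, 0.10, 0.20) else
        stats::runif(1, -0.05, 0)
      p <- learner_profile(
        participant_id = sprintf("P%02d", i),
        base_discriminability = stats::runif(1, 0.2, 0.4),
        learning_rate = rate,
        emg_leakage = stats::runif(1, 0.2, 0.8),
        chronometry_params = list(
          imagine_mean = stats::runif(1, 3.0, 3.8),
          speak_mean = stats::runif(1, 2.8, 3.4),
          sdlog = 0.15,
          drift_imagine = stats::rnorm(1, -0.05, 0.03),
          drift_speak = stats::rnorm(1, -0.05, 0.03))
      )
      attr(p, "is_learner") <- is_learner
      attr(p, "session_seed") <- mix_seed(seed, i, 59L)
      p
    })
  })
  structure(profiles, class = "bci_cohort",
            seed = as.integer(seed %% 2147483647L))
}

#' Simulate a mental-chronometry block
#'
#' Ten repetitions of each of the four conditions (modality speak/imagine x
#' syllable fo/gi), with durations drawn from a log-normal distribution
#' whose mean follows the profile's per-day drift. Log-normal is chosen as
#' the canonical positive, right-skewed model of timed-performance data.
#'
#' @param profile A [learner_profile()].
#' @param day Training day, 1-5.
#' @param seed Integer seed.
#' @return Data frame with 40 rows: `modality`, `syllable`, `rep`,
#'   `duration` (s).
#' @export
simulate_chronometry <- function(profile, day, seed = 1L) {
  if (!day %in% 1:5) stop_bci("day must be in 1..5")
  cp <- profile$chronometry_params
  if (cp$imagine_mean <= 0 || cp$speak_mean <= 0 || cp$sdlog < 0) {
    stop_bci("chronometry parameters must be positive")
  }
  grid <- expand.grid(rep = 1:10, syllable = c("fo", "gi"),
                      modality = c("imagine", "speak"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means <- ifelse(grid$modality == "imagine",
                  cp$imagine_mean + cp$drift_imagine * (day - 1),
                  cp$speak_mean + cp$drift_speak * (day - 1))
  means <- pmax(means, 0.2)
  dur <- with_seed(mix_seed(seed, day, 401L), {
    stats::rlnorm(nrow(grid), meanlog = log(means) - cp$sdlog^2 / 2,
                  sdlog = cp$sdlog)
  })
  data.frame(modality = grid$modality, syllable = grid$syllable,
             rep = grid$rep, duration = dur, stringsAsFactors = FALSE)
}

#' Simulate null participant-level band-power topographies
#'
#' Draws participant x scalp-channel matrices of baseline-vs-control percent
#' power change with no true effect but realistic spatial correlation
#' (smooth source mixing), for calibrating the sensor-space cluster test.
#'
#' @param n_participants Number of participants.
#' @param montage A [make_montage()] result.
#' @param sd Between-participant standard deviation of the channel values.
#' @param seed Integer seed.
#' @return Matrix participants x scalp channels.
#' @export
simulate_null_bandpower <- function(n_participants = 15,
                                    montage = make_montage(64),
                                    sd = 10, seed = 1L) {
  sc <- montage_channels(montage, "scalp")
  a <- mixing_matrix(montage)[sc, , drop = FALSE]
  with_seed(mix_seed(seed, 733L), {
    g <- matrix(stats::rnorm(n_participants * ncol(a)), n_participants)
    e <- matrix(stats::rnorm(n_participants * length(sc), 0, 0.5),
                n_participants)
    x <- g %*% t(a / sqrt(rowSums(a^2))) + e
    x <- x * sd
    colnames(x) <- sc
    x
  })
}
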