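# PSD feature extraction: sliding 500 ms windows stepped every 20 ms over
# the imagery period, single-window Hann periodogram, log-scaled power at
# the 2 Hz frequency grid. The canonical feature index is channel-major,
# frequency ascending.

#' Feature-extraction configuration
#'
#' A 500 ms window at 512 Hz has a natural 2 Hz periodogram bin spacing;
#' the 35-bin grid {2, 4, ..., 70} Hz is the unique grid reconciling the
#' 1-70 Hz range, the 2 Hz resolution, and 35 frequencies per channel. The
#' 20 ms step gives a 50 Hz decoder update rate (windows overlap by
#' 480 ms), consistent with continuous feedback.
#'
#' @param window Window length in seconds (default 0.5).
#' @param hop Window step in seconds (default 0.02).
#' @param fmin,fmax Frequency range in Hz (defaults 1 and 70).
#' @param resolution Frequency bin spacing in Hz (default 2).
#' @param log_floor Power floor (µV²/Hz) applied before the log transform.
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(window = 0.5, hop = 0.02, fmin = 1, fmax = 70,
                           resolution = 2, log_floor = 1e-12) {
  if (window * resolution < 1) {
    stop_bci("frequency grid not resolvable: window x resolution < 1")
  }
  structure(list(window = window, hop = hop, fmin = fmin, fmax = fmax,
                 resolution = resolution, log_floor = log_floor),
            class = "feature_config")
}

# The frequency grid: resolution, 2*resolution, ..., fmax.
feature_freqs <- function(config) {
  seq(config$resolution, config$fmax, by = config$resolution)
}

#' Build the canonical channel-frequency feature index
#'
#' With the default 64-channel montage (61 post-exclusion scalp channels)
#' and default grid this yields 61 x 35 = 2135 channel-frequency pairs,
#' ordered channel-major with frequency ascending.
#'
#' @param montage A [make_montage()] result.
#' @param config A [feature_config()].
#' @param channels Which channel roles to index: `"scalp"` (default),
#'   `"emg"`, or `"all"` (scalp + EMG).
#' @return Data frame (`channel`, `freq`, `group`) of class
#'   `feature_index`.
#' @export
build_feature_index <- function(montage, config = feature_config(),
                                channels = "scalp") {
  chans <- switch(channels,
                  scalp = montage_channels(montage, "scalp"),
                  emg = montage_channels(montage, "emg"),
                  all = c(montage_channels(montage, "scalp"),
                          montage_channels(montage, "emg")),
                  stop_bci("unknown channel selection '%s'", channels))
  if (length(chans) == 0) stop_bci("empty channel set")
  freqs <- feature_freqs(config)
  idx <- data.frame(
    channel = rep(chans, each = length(freqs)),
    freq = rep(freqs, length(chans)),
    stringsAsFactors = FALSE
  )
  grp <- as.character(montage$group[match(idx$channel, montage$labels)])
  idx$group <- grp
  class(idx) <- c("feature_index", "data.frame")
  idx
}

#' Sliding-window onsets within a segment
#'
#' Onsets are laid out on the time axis at 0, hop, 2*hop, ... such that each
#' window lies fully inside the segment (onsets are converted to sample
#' indices by rounding, which keeps the window count exact even when the
#' hop is not an integer number of samples).
#'
#' @param duration Segment duration in seconds.
#' @param config A [feature_config()].
#' @return Numeric vector of onsets in seconds (length 0 with a warning if
#'   the segment is shorter than one window).
#' @export
sliding_windows <- function(duration, config = feature_config()) {
  if (duration < config$window - 1e-9) {
    warning("segment shorter than one window; no windows returned")
    return(numeric(0))
  }
  n <- floor((duration - config$window) / config$hop + 1e-9) + 1
  (seq_len(n) - 1) * config$hop
}

# Hann periodogram of one window: matrix channels x wlen -> one-sided PSD
# (µV²/Hz) at the configured grid, log10-transformed with floor.
psd_window <- function(win, fs, config) {
  wlen <- ncol(win)
  h <- 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1)))
  scale <- 2 / (fs * sum(h^2))
  sp <- stats::mvfft(t(win * rep(h, each = nrow(win))))
  freqs <- feature_freqs(config)
  bins <- round(freqs * wlen / fs) + 1L
  p <- (Mod(sp[bins, , drop = FALSE])^2) * scale
  log10(pmax(p, config$log_floor))  # freq x channel
}

#' PSD feature vector of a single window
#'
#' @param win Matrix channels x samples covering exactly one window.
#' @param fs Sampling rate in Hz.
#' @param config A [feature_config()].
#' @return Named numeric vector over the channel-major feature index.
#' @export
psd_features <- function(win, fs = 512, config = feature_config()) {
  if (!all(is.finite(win))) stop_bci("non-finite input window")
  if (ncol(win) != round(config$window * fs)) {
    stop_bci("window must have %d samples", round(config$window * fs))
  }
  p <- psd_window(win, fs, config)  # freq x channel
  v <- as.vector(p)                 # channel-major after flattening f-major per channel
  names(v) <- paste(rep(rownames(win), each = nrow(p)),
                    rep(feature_freqs(config), ncol(p)), sep = "_")
  v
}

#' Extract the feature matrix of an epoch set
#'
#' Slides windows over `[tmin, tmax]` (relative to imagery onset) of every
#' epoch and computes the log-PSD feature vector of each window.
#'
#' @param epochs An `epoch_set`.
#' @param config A [feature_config()].
#' @param channels Channel selection passed to [build_feature_index()].
#' @param tmin,tmax Segment limits in seconds (defaults 0 and 5: the
#'   imagery/control period).
#' @return Object of class `feature_matrix`: `x` (windows x features),
#'   `index` (feature index), `meta` (per-window trial, onset, label).
#' @export
extract_features <- function(epochs, config = feature_config(),
                             channels = "scalp", tmin = 0, tmax = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  idx <- build_feature_index(epochs$montage, config, channels)
  chans <- unique(idx$channel)
  onsets <- sliding_windows(tmax - tmin, config)
  if (length(onsets) == 0) {
    return(structure(list(x = matrix(0, 0, nrow(idx)), index = idx,
                          meta = data.frame()), class = "feature_matrix"))
  }
  wlen <- round(config$window * fs)
  seg0 <- which.min(abs(epochs$times - tmin))
  starts <- seg0 + round(onsets * fs)
  ntr <- dim(epochs$data)[1]
  nwin <- length(onsets)
  nfreq <- length(feature_freqs(config))
  x <- matrix(0, ntr * nwin, nrow(idx))
  h <- 0.5 * (1 - cos(2 * pi * seq_len(wlen) / (wlen + 1)))
  scale <- 2 / (fs * sum(h^2))
  bins <- round(feature_freqs(config) * wlen / fs) + 1L
  for (i in seq_len(ntr)) {
    seg <- epochs$data[i, chans, , drop = FALSE][1, , , drop = TRUE]
    if (length(chans) == 1) seg <- matrix(seg, nrow = 1)
    rows <- (i - 1) * nwin + seq_len(nwin)
    for (ci in seq_along(chans)) {
      m <- vapply(starts, function(s) seg[ci, s:(s + wlen - 1)],
                  numeric(wlen))
      p <- (Mod(stats::mvfft(m * h)[bins, , drop = FALSE])^2) * scale
      cols <- (ci - 1) * nfreq + seq_len(nfreq)
      x[rows, cols] <- t(log10(pmax(p, config$log_floor)))
    }
  }
  colnames(x) <- paste(idx$channel, idx$freq, sep = "_")
  meta <- data.frame(
    trial = rep(epochs$info$trial, each = nwin),
    onset = rep(onsets, ntr) + tmin,
    label = rep(epochs$info$class, each = nwin),
    stringsAsFactors = FALSE
  )
  structure(list(x = x, index = idx, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d channels x %d freqs)\n",
              nrow(x$x), ncol(x$x), length(unique(x$index$channel)),
              length(unique(x$index$freq))))
  invisible(x)
}

#' Restrict a feature matrix to its EMG channels
#'
#' Keeps only columns belonging to EMG electrodes (2 channels x 35 bins =
#' 70 features with the default grid), for the EMG-restricted decoding
#' control analysis. The input must have been extracted with
#' `channels = "all"` or `"emg"`.
#'
#' @param features A `feature_matrix`.
#' @return A `feature_matrix` over the EMG columns only.
#' @export
restrict_to_emg <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  keep <- features$index$group == "emg"
  if (!any(keep)) {
    stop_bci("no EMG channels in feature matrix; extract with channels = 'all'")
  }
  out <- features
  out$x <- features$x[, keep, drop = FALSE]
  out$index <- features$index[keep, , drop = FALSE]
  out
}

#' Write a feature matrix to CSV
#' @param features A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  df <- cbind(features$meta, as.data.frame(features$x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
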