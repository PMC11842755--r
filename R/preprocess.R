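# Offline preprocessing: zero-phase band-pass filtering, epoching around
# imagery onset, common-average re-referencing, and an automated
# artifact-rejection rule with neighbour interpolation.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the effective response is the squared magnitude
#' of the analogue prototype and the group delay is zero.
#'
#' The `"fft"` method applies the Butterworth's squared magnitude response
#' (the exact steady-state response of forward-backward filtering) to the
#' whole recording in the frequency domain, all channels in one pass; it
#' differs from the time-domain pass only in edge handling and is the fast
#' default for long continuous recordings. `"filtfilt"` runs
#' `signal::filtfilt` per channel.
#'
#' @param recording A `bci_recording`.
#' @param low,high Cutoff frequencies in Hz (defaults 1 and 70).
#' @param order Filter order of the one-pass prototype (default 4, i.e.
#'   effective order 8 after the forward-backward pass).
#' @param method `"fft"` (default) or `"filtfilt"`.
#' @return Filtered `bci_recording`.
#' @export
bandpass <- function(recording, low = 1, high = 70, order = 4,
                     method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  stopifnot(inherits(recording, "bci_recording"))
  fs <- recording$fs
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop_bci("cutoffs must satisfy 0 < low < high < fs/2 = %.1f", fs / 2)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  if (method == "filtfilt") {
    for (i in seq_len(nrow(out$data))) {
      out$data[i, ] <- signal::filtfilt(bf, out$data[i, ])
    }
  } else {
    n <- ncol(out$data)
    z <- exp(-2i * pi * (seq_len(n) - 1) / n)   # e^{-i w}, rad/sample
    horner <- function(coef) {
      acc <- rep(coef[length(coef)] + 0i, n)
      for (k in rev(seq_len(length(coef) - 1))) acc <- acc * z + coef[k]
      acc
    }
    h2 <- Mod(horner(bf$b) / horner(bf$a))^2    # zero-phase response
    spec <- stats::mvfft(t(out$data)) * h2
    out$data <- t(Re(stats::mvfft(spec, inverse = TRUE)) / n)
    dimnames(out$data) <- dimnames(recording$data)
  }
  out
}

#' Cut a recording into imagery-locked epochs
#'
#' One epoch per scheduled trial, spanning `tmin` to `tmax` seconds around
#' imagery onset (default -4 to +8, i.e. 12 s). Trials whose window falls
#' outside the recording are dropped and logged.
#'
#' @param recording A `bci_recording`.
#' @param schedule A `trial_schedule`.
#' @param tmin,tmax Epoch limits in seconds relative to imagery onset.
#' @return Object of class `epoch_set`: `data` (trials x channels x
#'   samples), `times`, `fs`, `montage`, `info` (per-trial class/block),
#'   `rejection_log`.
#' @export
epoch_trials <- function(recording, schedule, tmin = -4, tmax = 8) {
  stopifnot(inherits(recording, "bci_recording"))
  fs <- recording$fs
  nsamp <- round((tmax - tmin) * fs)
  offs <- round(tmin * fs)
  n_total <- ncol(recording$data)
  keep <- logical(nrow(schedule))
  log <- list()
  slices <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    i0 <- round(schedule$t_imagery[i] * fs) + offs + 1L
    i1 <- i0 + nsamp - 1L
    if (i0 < 1 || i1 > n_total) {
      log[[length(log) + 1]] <- list(type = "epoch", trial = schedule$trial[i],
                                     reason = "window outside recording")
      next
    }
    keep[i] <- TRUE
    slices[[i]] <- recording$data[, i0:i1, drop = FALSE]
  }
  kept <- which(keep)
  data <- array(0, c(length(kept), nrow(recording$data), nsamp),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (j in seq_along(kept)) data[j, , ] <- slices[[kept[j]]]
  structure(list(
    data = data,
    times = tmin + (seq_len(nsamp) - 1) / fs,
    fs = fs,
    montage = recording$montage,
    info = schedule[kept, c("trial", "class", "block"), drop = FALSE],
    rejection_log = log
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%.1f..%.1f s)\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  if (length(x$rejection_log)) {
    cat(sprintf("  %d rejection-log entries\n", length(x$rejection_log)))
  }
  invisible(x)
}

#' Re-reference epochs to the common average
#'
#' Subtracts, at every sample, the mean over scalp channels from all EEG
#' channels (scalp + mastoid). EMG and reference channels are untouched.
#' Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return Re-referenced `epoch_set`.
#' @export
rereference_common_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  mo <- epochs$montage
  sc <- intersect(montage_channels(mo, "scalp"), dimnames(epochs$data)[[2]])
  if (length(sc) < 2) stop_bci("need at least 2 scalp channels")
  eeg <- intersect(montage_channels(mo, "eeg"), dimnames(epochs$data)[[2]])
  out <- epochs
  for (i in seq_len(dim(out$data)[1])) {
    m <- colMeans(out$data[i, sc, , drop = FALSE][1, , ])
    out$data[i, eeg, ] <- sweep(out$data[i, eeg, , drop = FALSE][1, , ],
                                2, m)
  }
  out
}

#' Automated artifact rejection with neighbour interpolation
#'
#' Replaces inspection-based cleaning with a deterministic rule: per-epoch /
#' per-channel peak-to-peak amplitudes are summarized robustly (median of
#' log amplitude), converted to robust z-scores (median/MAD), and entries
#' exceeding `z_thresh` are flagged. Flagged epochs are dropped; flagged
#' channels are reconstructed by inverse-great-circle-distance weighting
#' over their good montage neighbours. All actions are logged.
#'
#' @param epochs An `epoch_set`.
#' @param z_thresh Robust z-score threshold (> 0, default 5).
#' @return Cleaned `epoch_set` with updated `rejection_log`.
#' @export
reject_and_interpolate <- function(epochs, z_thresh = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (z_thresh <= 0) stop_bci("z_thresh must be > 0")
  mo <- epochs$montage
  eeg <- intersect(montage_channels(mo, "eeg"), dimnames(epochs$data)[[2]])
  x <- epochs$data[, eeg, , drop = FALSE]
  ntr <- dim(x)[1]
  ptp <- matrix(0, ntr, length(eeg), dimnames = list(NULL, eeg))
  for (i in seq_len(ntr)) {
    xi <- x[i, , , drop = FALSE][1, , ]
    ptp[i, ] <- apply(xi, 1, function(v) max(v) - min(v))
  }
  lptp <- log(pmax(ptp, .Machine$double.eps))
  robust_z <- function(v) {
    med <- stats::median(v)
    s <- stats::mad(v)
    if (s < 1e-12) s <- stats::sd(v) + 1e-12
    (v - med) / s
  }
  ch_score <- apply(lptp, 2, stats::median)
  bad_ch <- names(which(robust_z(ch_score) > z_thresh))
  if (length(bad_ch) > length(eeg) / 2) {
    stop_bci("more than half the channels flagged (%d of %d); aborting",
             length(bad_ch), length(eeg))
  }
  good_ch <- setdiff(eeg, bad_ch)
  ep_score <- apply(lptp[, good_ch, drop = FALSE], 1, stats::median)
  bad_ep <- which(robust_z(ep_score) > z_thresh)

  out <- epochs
  log <- epochs$rejection_log
  if (length(bad_ep)) {
    log <- c(log, lapply(bad_ep, function(i) {
      list(type = "epoch", trial = epochs$info$trial[i],
           reason = sprintf("robust z %.1f > %.1f", robust_z(ep_score)[i],
                            z_thresh))
    }))
    keep <- setdiff(seq_len(ntr), bad_ep)
    out$data <- out$data[keep, , , drop = FALSE]
    out$info <- out$info[keep, , drop = FALSE]
  }
  if (length(bad_ch)) {
    pos <- mo$positions
    for (ch in bad_ch) {
      nb <- names(which(mo$adjacency[ch, ]))
      nb <- intersect(nb, good_ch)
      if (length(nb) == 0) nb <- good_ch
      ang <- acos(pmin(pmax(drop(pos[nb, , drop = FALSE] %*% pos[ch, ]),
                            -1), 1))
      w <- 1 / pmax(ang, 1e-6)
      w <- w / sum(w)
      for (i in seq_len(dim(out$data)[1])) {
        out$data[i, ch, ] <- drop(w %*% out$data[i, nb, , drop = FALSE][1, , ])
      }
      log <- c(log, list(list(type = "channel", channel = ch,
                              reason = sprintf("robust z > %.1f; interpolated from %s",
                                               z_thresh,
                                               paste(nb, collapse = ",")))))
    }
  }
  out$rejection_log <- log
  out
}

#' Write a rejection log as JSON
#' @param epochs An `epoch_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(epochs, path) {
  jsonlite::write_json(epochs$rejection_log, path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
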