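# File interfaces: a minimal EDF (European Data Format) writer/reader for
# continuous recordings, CSV helpers for schedules and chronometry tables,
# and the YAML generator configuration.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' Minimal EDF (not EDF+) writer: ASCII header, one data record per
#' second, 16-bit little-endian samples scaled per channel to the signal's
#' physical range. Adequate for interchange of the simulated sessions.
#'
#' @param recording A `bci_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "bci_recording"))
  x <- recording$data
  fs <- recording$fs
  ns <- nrow(x)
  n_rec <- floor(ncol(x) / fs)
  x <- x[, seq_len(n_rec * fs), drop = FALSE]
  # physical range rounded exactly as it is printed in the header, so the
  # reader's rescaling uses identical limits
  pmin_ <- as.numeric(format(apply(x, 1, min), digits = 6))
  pmax_ <- as.numeric(format(apply(x, 1, max), digits = 6))
  pmin_ <- pmin_ - abs(pmin_) * 1e-5 - 1e-9   # keep data inside the range
  pmax_ <- pmax_ + abs(pmax_) * 1e-5 + 1e-9
  pmin_ <- as.numeric(format(pmin_, digits = 6))
  pmax_ <- as.numeric(format(pmax_, digits = 6))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)                                  # version
  wr(recording$meta$participant %||% "X", 80) # patient id
  wr("bcilearn simulated session", 80)        # recording id
  wr("01.01.26", 8); wr("00.00.00", 8)        # start date/time
  wr(as.character(256 * (ns + 1)), 8)         # header bytes
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)                                  # record duration (s)
  wr(as.character(ns), 4)
  for (l in rownames(x)) wr(l, 16)
  for (i in seq_len(ns)) wr("simulated", 80)  # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(pmin_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(format(pmax_[i], digits = 6), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)           # prefiltering
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (i in seq_len(ns)) {
      dig <- round((x[i, idx] - pmin_[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param montage Optional `bci_montage` to attach.
#' @return A `bci_recording` (events empty).
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  fs <- spr[1] / dur
  x <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      idx <- (r - 1) * spr[i] + seq_len(spr[i])
      x[i, idx] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  structure(list(data = x, fs = fs, montage = montage,
                 events = data.frame(sample = integer(0),
                                     marker = character(0)),
                 meta = list(source = path)),
            class = "bci_recording")
}

#' Default generator configuration
#'
#' All tunable generator and analysis parameters in one list, suitable for
#' round-tripping through YAML; every source of randomness derives from
#' its `seed`.
#'
#' @param seed Master seed.
#' @return Named list.
#' @export
bci_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    fs = 512,
    montage_size = 64,
    n_per_class = 40,
    rest_dur = 5,
    days = 5,
    feature = unclass(feature_config()),
    decoder = list(num_trees = 500, k_folds = 8),
    feedback = list(delta = 1 / 250, timeout = 5, mode = "continuous"),
    bands = band_spec(),
    baseline = c(-3, -2),
    cohort = list(n_participants = 15, n_learners = 11)
  )
}

#' Write / read the generator configuration as YAML
#' @param config A config list ([bci_config()]).
#' @param path File path.
#' @return `path` (write) or the config list (read).
#' @export
write_bci_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_bci_config
#' @export
read_bci_config <- function(path) {
  yaml::read_yaml(path)
}
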