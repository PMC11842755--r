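# A short synthetic recording with known content for filter tests.
tone_recording <- function(freqs, amps, dur = 8, fs = 512) {
  m <- tiny_montage()
  tt <- seq_len(dur * fs) / fs
  sig <- rowSums(vapply(seq_along(freqs),
                        function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                        numeric(length(tt))))
  x <- matrix(rep(sig, each = length(m$labels)), length(m$labels),
              dimnames = list(m$labels, NULL))
  structure(list(data = x, fs = fs, montage = m,
                 events = data.frame(sample = integer(0),
                                     marker = character(0)),
                 meta = list()),
            class = "bci_recording")
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  rec10 <- tone_recording(10, 1)
  out <- bandpass(rec10)
  i <- 1024:3072  # interior, away from edges
  expect_gt(sd(out$data[1, i]) / sd(rec10$data[1, i]), 0.95)
  # phase: zero-lag correlation essentially 1
  expect_gt(cor(out$data[1, i], rec10$data[1, i]), 0.999)
  rec100 <- tone_recording(100, 1)
  out100 <- bandpass(rec100)
  expect_lt(sd(out100$data[1, i]) / sd(rec100$data[1, i]), 0.10)
  expect_error(bandpass(rec10, low = 1, high = 300), "Nyquist|fs/2")
})

test_that("forward-backward filtering is zero-phase (symmetric impulse response)", {
  m <- tiny_montage()
  n <- 4096
  x <- matrix(0, length(m$labels), n, dimnames = list(m$labels, NULL))
  x[, n / 2] <- 1
  rec <- structure(list(data = x, fs = 512, montage = m,
                        events = data.frame(sample = integer(0),
                                            marker = character(0)),
                        meta = list()), class = "bci_recording")
  for (method in c("fft", "filtfilt")) {
    h <- bandpass(rec, method = method)$data[1, ]
    k <- 200
    left <- h[(n / 2 - k):(n / 2 - 1)]
    right <- h[(n / 2 + 1):(n / 2 + k)]
    expect_lt(max(abs(rev(left) - right)), 1e-8)
  }
})

test_that("fft and filtfilt band-pass agree away from the edges", {
  prof <- null_profile()
  rec <- simulate_session(prof, 1, "offline", tiny_montage(),
                          n_per_class = 4, rest_dur = 1, seed = 5)$recording
  a <- bandpass(rec, method = "fft")
  b <- bandpass(rec, method = "filtfilt")
  i <- 3000:(ncol(rec$data) - 3000)
  expect_lt(max(abs(a$data[2, i] - b$data[2, i])), 1e-4 * sd(b$data[2, i]))
})

test_that("epoching yields 12 s epochs of 6144 samples with labels carried over", {
  prof <- null_profile()
  ses <- simulate_session(prof, 1, "offline", tiny_montage(),
                          n_per_class = 4, rest_dur = 1, seed = 6)
  ep <- epoch_trials(ses$recording, ses$schedule)
  expect_equal(dim(ep$data)[1], 8)
  expect_equal(dim(ep$data)[3], 6144)
  expect_equal(round((max(ep$times) - min(ep$times)) * 512) + 1, 6144)
  expect_identical(ep$info$class, ses$schedule$class)
  # a trial pushed past the recording end is dropped and logged
  sched2 <- ses$schedule
  sched2$t_imagery[8] <- ncol(ses$recording$data) / 512 - 2
  ep2 <- epoch_trials(ses$recording, sched2)
  expect_equal(dim(ep2$data)[1], 7)
  expect_equal(length(ep2$rejection_log), 1)
  expect_match(ep2$rejection_log[[1]]$reason, "outside")
})

test_that("filtering then epoching commutes with epoching pre-filtered data", {
  prof <- null_profile()
  ses <- simulate_session(prof, 1, "offline", tiny_montage(),
                          n_per_class = 4, rest_dur = 1, seed = 7)
  a <- epoch_trials(bandpass(ses$recording), ses$schedule, -1, 6)
  b <- bandpass(ses$recording)  # same filtered copy, epoch later
  bb <- epoch_trials(b, ses$schedule, -1, 6)
  expect_equal(a$data, bb$data, tolerance = 1e-12)
})

test_that("common-average re-referencing zeroes the scalp mean and is idempotent", {
  ep <- strong_epochs()
  ref <- rereference_common_average(ep)
  sc <- montage_channels(ep$montage, "scalp")
  m1 <- colMeans(ref$data[1, sc, ])
  expect_lt(max(abs(m1)), 1e-9 * sd(ref$data[1, sc[1], ]))
  ref2 <- rereference_common_average(ref)
  expect_equal(ref$data, ref2$data, tolerance = 1e-12)
  # EMG channels untouched
  expect_identical(ref$data[, "EMG1", ], ep$data[, "EMG1", ])
  # zero-mean toy input is a fixed point
  toy <- ep
  toy$data[] <- 0
  toy$data[, sc[1], ] <- 1
  toy$data[, sc[2], ] <- -1
  fixed <- rereference_common_average(toy)
  expect_equal(fixed$data[, sc[1:2], ],
               toy$data[, sc[1:2], ] - mean(c(1, -1, rep(0, length(sc) - 2))),
               tolerance = 1e-12)
})

test_that("planted outliers are rejected or interpolated; clean data untouched", {
  ep <- strong_epochs()
  clean <- reject_and_interpolate(ep, z_thresh = 5)
  expect_equal(dim(clean$data), dim(ep$data))
  expect_equal(length(clean$rejection_log), length(ep$rejection_log))

  bad_ch <- ep
  orig <- bad_ch$data[, "C4", ]
  bad_ch$data[, "C4", ] <- bad_ch$data[, "C4", ] * 50
  fixed <- reject_and_interpolate(bad_ch, z_thresh = 5)
  chans <- vapply(Filter(function(l) l$type == "channel",
                         fixed$rejection_log), `[[`, character(1), "channel")
  expect_identical(chans, "C4")
  expect_gt(cor(as.vector(fixed$data[, "C4", ]), as.vector(orig)), 0.8)

  bad_ep <- ep
  bad_ep$data[3, , ] <- bad_ep$data[3, , ] * 10
  dropped <- reject_and_interpolate(bad_ep, z_thresh = 5)
  expect_equal(dim(dropped$data)[1], dim(ep$data)[1] - 1)
  expect_false(3 %in% match(dropped$info$trial, ep$info$trial))

  expect_error(reject_and_interpolate(ep, z_thresh = 0), "> 0")
})
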