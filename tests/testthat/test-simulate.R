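test_that("default schedule has 40 trials per class in 4 balanced blocks", {
  s <- make_schedule()
  expect_equal(sum(s$class == "fo"), 40)
  expect_equal(sum(s$class == "gi"), 40)
  tab <- table(s$class, s$block)
  expect_true(all(tab == 10))
  # phases are ordered and non-overlapping within each trial
  expect_true(all(s$t_fixation > s$t_start))
  expect_true(all(s$t_cue > s$t_fixation))
  expect_true(all(s$t_imagery > s$t_cue))
  expect_true(all(diff(s$t_start) >= s$imagery_dur[1]))
})

test_that("simulated sessions are bit-reproducible and finite", {
  prof <- learner_profile()
  m <- tiny_montage()
  a <- simulate_session(prof, 2, "offline", m, n_per_class = 4,
                        rest_dur = 1, seed = 9)
  b <- simulate_session(prof, 2, "offline", m, n_per_class = 4,
                        rest_dur = 1, seed = 9)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$schedule, b$schedule)
  expect_true(all(is.finite(a$recording$data)))
  expect_equal(a$recording$fs, 512)
  # events strictly increasing and within range
  ev <- a$recording$events$sample
  expect_true(all(diff(ev) > 0))
  expect_true(max(ev) <= ncol(a$recording$data))
  # different session type gives different data
  onl <- simulate_session(prof, 2, "online", m, n_per_class = 4,
                          rest_dur = 1, seed = 9)
  expect_false(identical(a$recording$data, onl$recording$data))
})

test_that("zero discriminability yields class-indistinguishable band power", {
  ep <- null_epochs()
  # band power at the planted locus channel, 8-16 Hz, per trial
  fm <- extract_features(ep, feature_config(hop = 0.5))
  cols <- fm$index$channel == "C3" & fm$index$freq >= 8 & fm$index$freq <= 16
  bp <- rowMeans(fm$x[, cols, drop = FALSE])
  trial_bp <- tapply(bp, fm$meta$trial, mean)
  trial_cls <- fm$meta$label[!duplicated(fm$meta$trial)]
  p <- t.test(trial_bp[trial_cls == "fo"], trial_bp[trial_cls == "gi"])$p.value
  expect_gt(p, 0.01)
})

test_that("discriminability grows with day and is floored at zero", {
  prof <- learner_profile(base_discriminability = 0.2, learning_rate = -0.3)
  expect_equal(discriminability(prof, 1), 0.2)
  expect_equal(discriminability(prof, 3), 0)
  prof2 <- learner_profile(base_discriminability = 0.1, learning_rate = 0.2)
  expect_equal(discriminability(prof2, 5), 0.9)
  expect_error(learner_profile(base_discriminability = -1), ">= 0")
  expect_error(learner_profile(base_discriminability = NaN), "non-finite")
})

test_that("cohorts have the requested learner split and are reproducible", {
  co <- simulate_cohort(15, 11, seed = 7)
  rates <- vapply(co, function(p) p$learning_rate, numeric(1))
  expect_equal(sum(rates > 0), 11)
  expect_true(all(rates[12:15] <= 0))
  co2 <- simulate_cohort(15, 11, seed = 7)
  expect_identical(co, co2)
  single <- simulate_cohort(1, 0, seed = 1)
  expect_equal(length(single), 1)
  expect_lte(single[[1]]$learning_rate, 0)
  expect_error(simulate_cohort(0, 0), ">= 1")
  expect_error(simulate_cohort(3, 5), "<=")
})

test_that("chronometry tables have 40 rows, are reproducible, and honour isochrony", {
  prof <- learner_profile()
  tab <- simulate_chronometry(prof, 3, seed = 4)
  expect_equal(nrow(tab), 40)
  expect_equal(as.vector(table(tab$modality)), c(20L, 20L))
  expect_true(all(tab$duration > 0))
  expect_identical(tab, simulate_chronometry(prof, 3, seed = 4))
  # zero dispersion + equal means -> exact isochrony
  iso_prof <- learner_profile(chronometry_params = list(
    imagine_mean = 3, speak_mean = 3, sdlog = 0,
    drift_imagine = 0, drift_speak = 0))
  t0 <- simulate_chronometry(iso_prof, 1, seed = 1)
  im <- mean(t0$duration[t0$modality == "imagine"])
  sp <- mean(t0$duration[t0$modality == "speak"])
  expect_equal(deviation_from_isochrony(im, sp), 0)
})

test_that("epoch-level generator matches the session pipeline structurally", {
  ep <- strong_epochs()
  expect_s3_class(ep, "epoch_set")
  expect_equal(dim(ep$data)[1], 16)
  expect_equal(dim(ep$data)[3], 7 * 512)
  expect_identical(simulate_epoch_set(learner_profile(), 5, "offline",
                                      tiny_montage(), n_per_class = 8,
                                      seed = 42)$data, ep$data)
})
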