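# Small epoch sets with known oscillatory content for the TFR tests.
tone_epochs <- function(freq = 10, amp = 1, n_trials = 2, dur = 4, fs = 512,
                        noise = 0) {
  m <- tiny_montage()
  chans <- m$labels
  nsamp <- dur * fs
  times <- seq(-1, by = 1 / fs, length.out = nsamp)
  dat <- array(0, c(n_trials, length(chans), nsamp),
               dimnames = list(NULL, chans, NULL))
  for (i in seq_len(n_trials)) {
    sig <- amp * sin(2 * pi * freq * times)
    if (noise > 0) sig <- sig + rnorm(nsamp, 0, noise)
    dat[i, , ] <- matrix(rep(sig, each = length(chans)), length(chans))
  }
  structure(list(data = dat, times = times, fs = fs, montage = m,
                 info = data.frame(trial = seq_len(n_trials),
                                   class = rep(c("fo", "gi"),
                                               length.out = n_trials),
                                   block = 1),
                 rejection_log = list()),
            class = "epoch_set")
}

test_that("Morlet power localizes tones and scales quadratically", {
  ep <- tone_epochs(freq = 10)
  freqs <- seq(4, 30, 2)
  tfr <- morlet_tfr(ep, freqs = freqs, decim = 16)
  mid <- which.min(abs(tfr$times - 1))
  spec <- tfr$power[1, 1, , mid]
  expect_equal(freqs[which.max(spec)], 10)
  ep2 <- tone_epochs(freq = 10, amp = 2)
  tfr2 <- morlet_tfr(ep2, freqs = freqs, decim = 16)
  expect_equal(unname(tfr2$power[1, 1, 4, mid] / tfr$power[1, 1, 4, mid]),
               4, tolerance = 0.01)
  expect_error(morlet_tfr(ep, freqs = 0.2), "longer than epoch")
})

test_that("white-noise power is stationary across the epoch interior", {
  withr::with_seed(9, ep <- tone_epochs(freq = 10, amp = 0, n_trials = 16,
                                        noise = 1))
  tfr <- morlet_tfr(ep, freqs = c(10, 20, 40), decim = 16)
  interior <- which(tfr$times > -0.5 & tfr$times < 2.5)
  # average over trials, frequencies and 0.75 s time bins
  bins <- split(interior, ceiling(seq_along(interior) / 24))
  avg <- vapply(bins, function(i) mean(tfr$power[, 1, , i]), numeric(1))
  expect_lt((max(avg) - min(avg)) / mean(avg), 0.2)
})

test_that("baseline normalization yields percent change anchored at zero", {
  ep <- tone_epochs(freq = 10, n_trials = 2)
  tfr <- morlet_tfr(ep, freqs = c(10, 20), decim = 8)
  # constant-amplitude tone: percent change ~0 everywhere
  norm <- baseline_normalize(tfr, baseline = c(-0.8, -0.4))
  interior <- norm$times > -0.8 & norm$times < 2.5
  expect_lt(max(abs(norm$power[1, 1, 1, interior])), 5)
  # doubled post-onset amplitude -> +300% power after onset
  ep2 <- ep
  post <- ep2$times > 0
  ep2$data[, , post] <- ep2$data[, , post] * 2
  norm2 <- baseline_normalize(morlet_tfr(ep2, freqs = c(10, 20), decim = 8),
                              baseline = c(-0.8, -0.4))
  late <- norm2$times > 0.5 & norm2$times < 2.5
  expect_equal(mean(norm2$power[1, 1, 1, late]), 300, tolerance = 10)
  # mean over the baseline window of normalized values ~ 0
  bidx <- norm$times >= -0.8 & norm$times <= -0.4
  expect_lt(abs(mean(norm$power[1, 1, 1, bidx])), 1e-6)
  expect_error(baseline_normalize(tfr, baseline = c(-50, -40)), "baseline")
})

test_that("band averaging equals the brute-force mean over bins and window", {
  withr::with_seed(10, ep <- tone_epochs(amp = 0, n_trials = 3, noise = 1))
  tfr <- morlet_tfr(ep, freqs = seq(4, 40, 4), decim = 16)
  bands <- list(alpha = c(8, 13), beta = c(14, 26))
  ba <- band_average(tfr, bands, window = c(0, 2))
  fidx <- tfr$freqs >= 8 & tfr$freqs <= 13
  tidx <- tfr$times >= 0 & tfr$times <= 2
  expect_equal(ba[2, 3, "alpha"], mean(tfr$power[2, 3, fidx, tidx]),
               tolerance = 1e-12)
  expect_error(band_average(tfr, list(x = c(60, 70))), "empty band")
})

test_that("cluster test matches the exhaustive sign-flip oracle on a 3-channel toy", {
  adj <- chain_adjacency()
  withr::with_seed(11, {
    x <- matrix(rnorm(6 * 3, mean = c(1.2, 1.2, 0)), 6, 3, byrow = TRUE,
                dimnames = list(NULL, c("A", "B", "C")))
  })
  for (stat in c("size", "mass")) {
    res <- cluster_test_baseline(x, adj, stat = stat, exact = TRUE)
    oracle <- brute_cluster_test(x, adj, stat = stat)
    expect_equal(length(res$clusters), length(oracle))
    for (i in seq_along(oracle)) {
      expect_equal(res$clusters[[i]]$stat, oracle[[i]]$stat,
                   tolerance = 1e-9)
      expect_equal(res$clusters[[i]]$p, oracle[[i]]$p, tolerance = 1e-9)
    }
  }
})

test_that("planted topographic effects form significant clusters; weak ones do not", {
  m <- small_montage()
  adj <- scalp_adjacency(m)
  sc <- colnames(adj)
  withr::with_seed(12, {
    x <- matrix(rnorm(15 * length(sc)), 15, dimnames = list(NULL, sc))
    posterior <- c("C3", "Cz", "C4", "P3", "Pz", "P4")
    x[, posterior] <- x[, posterior] + 1.4
  })
  res <- cluster_test_baseline(x, adj, n_perm = 500, seed = 4)
  sig <- Filter(function(cl) cl$p < 0.05 && cl$sign > 0, res$clusters)
  expect_gte(length(sig), 1)
  expect_true(any(vapply(sig, function(cl) any(posterior %in% cl$channels),
                         logical(1))))
  # single-channel effect below the cluster-forming threshold: no cluster
  withr::with_seed(13, {
    x2 <- matrix(rnorm(15 * length(sc), 0, 1), 15,
                 dimnames = list(NULL, sc))
    x2[, "Cz"] <- x2[, "Cz"] + 0.3   # |t| stays below the threshold
  })
  res2 <- cluster_test_baseline(x2, adj, n_perm = 200, seed = 5)
  expect_true(all(vapply(res2$clusters,
                         function(cl) !"Cz" %in% cl$channels ||
                           cl$p >= 0.05, logical(1))))
})

test_that("trend cluster test finds planted day-increasing power", {
  m <- small_montage()
  adj <- scalp_adjacency(m)
  sc <- colnames(adj)
  withr::with_seed(14, {
    y <- array(rnorm(12 * length(sc) * 5), c(12, length(sc), 5),
               dimnames = list(NULL, sc, NULL))
    for (d in 1:5) y[, , d] <- y[, , d] + 0.8 * d  # global increase
  })
  res <- cluster_test_trend(y, adjacency = adj, n_perm = 500, seed = 6)
  sig <- Filter(function(cl) cl$p < 0.05 && cl$sign > 0, res$clusters)
  expect_gte(length(sig), 1)
  expect_gte(max(vapply(sig, `[[`, numeric(1), "size")), length(sc) / 2)
  expect_true(all(vapply(res$clusters, `[[`, numeric(1), "p") >= 1 / 501))
  # permutation engine is seed-deterministic
  res2 <- cluster_test_trend(y, adjacency = adj, n_perm = 500, seed = 6)
  expect_identical(vapply(res$clusters, `[[`, numeric(1), "p"),
                   vapply(res2$clusters, `[[`, numeric(1), "p"))
})

test_that("cluster membership is invariant to channel reordering", {
  m <- small_montage()
  adj <- scalp_adjacency(m)
  sc <- colnames(adj)
  withr::with_seed(15, {
    x <- simulate_null_bandpower(12, m, sd = 4, seed = 9)
    x[, c("F3", "Fz", "F4")] <- x[, c("F3", "Fz", "F4")] + 7
    perm <- sample(length(sc))
  })
  res <- cluster_test_baseline(x, adj, n_perm = 300, seed = 7)
  res_p <- cluster_test_baseline(x[, perm], adj[perm, perm], n_perm = 300,
                                 seed = 7)
  chans <- lapply(res$clusters, function(cl) sort(cl$channels))
  chans_p <- lapply(res_p$clusters, function(cl) sort(cl$channels))
  expect_setequal(vapply(chans, paste, character(1), collapse = ","),
                  vapply(chans_p, paste, character(1), collapse = ","))
})

test_that("power x training interaction recovers planted coupling and its sign", {
  m <- tiny_montage()
  adj <- scalp_adjacency(m)
  sc <- colnames(adj)
  np <- 12
  make_data <- function(sign, seed) {
    withr::with_seed(seed, {
      power <- array(rnorm(np * length(sc) * 5), c(np, length(sc), 5),
                     dimnames = list(NULL, sc, NULL))
      perf <- expand.grid(participant = sprintf("P%02d", 1:np), day = 1:5)
      perf$value <- 55 + rnorm(nrow(perf), 0, 1)
      cw <- perf$day - 3
      # coupling between C3 power and performance that grows with day
      idx <- cbind(match(perf$participant, sprintf("P%02d", 1:np)), 0,
                   perf$day)
      for (ch in c("C3", "Cz")) {
        idx[, 2] <- which(sc == ch)
        perf$value <- perf$value + sign * 1.2 * cw * power[idx]
      }
      list(power = power, perf = perf)
    })
  }
  up <- make_data(+1, 16)
  res <- brain_behavior_interaction(up$perf, up$power, adj, n_perm = 300,
                                    stat = "mass", seed = 8)
  sig <- Filter(function(cl) cl$p < 0.05, res$clusters)
  expect_gte(length(sig), 1)
  expect_true(any(vapply(sig, function(cl) "C3" %in% cl$channels,
                         logical(1))))
  expect_gt(res$t[["C3"]], 0)
  dn <- make_data(-1, 16)
  res_dn <- brain_behavior_interaction(dn$perf, dn$power, adj, n_perm = 50,
                                       stat = "mass", seed = 8)
  expect_lt(res_dn$t[["C3"]], 0)
})
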