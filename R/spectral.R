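# Time-frequency analysis and sensor-space cluster-based permutation
# statistics: Morlet decomposition, single-trial percent-change baseline
# normalization, band/window averaging, and three cluster tests (vs
# baseline, day trend, brain-behaviour interaction).

#' Canonical frequency bands
#' @return Named list of Hz intervals: theta 4-7, alpha 8-13, beta 14-26,
#'   low-gamma 27-40, high-gamma 41-70.
#' @export
band_spec <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 26),
       low_gamma = c(27, 40), high_gamma = c(41, 70))
}

#' Morlet time-frequency power
#'
#' Complex Morlet wavelet decomposition of an epoch set; power is the
#' squared magnitude. The number of cycles increases linearly from 3 at
#' 4 Hz to 7 at 70 Hz (clamped to that range), balancing temporal
#' resolution at low frequencies against spectral resolution at high ones.
#'
#' @param epochs An `epoch_set`.
#' @param freqs Frequency grid in Hz (default `seq(2, 70, 2)`).
#' @param n_cycles Cycles per frequency (default the linear ramp above).
#' @param decim Temporal decimation factor of the output (default 8).
#' @param channels Channel labels to decompose (default scalp channels).
#' @return Object of class `bci_tfr`: `power` array (trials x channels x
#'   freqs x time), `times`, `freqs`, `channels`, `info`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(2, 70, 2), n_cycles = NULL,
                       decim = 8, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  channels <- channels %||%
    intersect(montage_channels(epochs$montage, "scalp"),
              dimnames(epochs$data)[[2]])
  n_cycles <- n_cycles %||% pmin(7, pmax(3, 3 + (freqs - 4) * 4 / 66))
  nsamp <- dim(epochs$data)[3]
  ntr <- dim(epochs$data)[1]
  nch <- length(channels)
  sigma_t <- n_cycles / (2 * pi * freqs)
  half <- ceiling(3 * sigma_t * fs)
  too_long <- 2 * half + 1 > nsamp
  if (any(too_long)) {
    stop_bci("wavelet longer than epoch at %.3g Hz (need %d samples, have %d)",
             freqs[which(too_long)[1]], 2 * max(half[too_long]) + 1, nsamp)
  }
  nfft <- stats::nextn(nsamp + 2 * max(half), 2)
  # stack all trial x channel series as columns of one FFT call
  d <- matrix(0, nfft, ntr * nch)
  for (i in seq_len(ntr)) {
    d[seq_len(nsamp), (i - 1) * nch + seq_len(nch)] <-
      t(epochs$data[i, channels, , drop = FALSE][1, , ])
  }
  df <- stats::mvfft(d)
  tidx <- seq(1, nsamp, by = decim)
  power <- array(0, c(ntr, nch, length(freqs), length(tidx)),
                 dimnames = list(NULL, channels, NULL, NULL))
  for (k in seq_along(freqs)) {
    tt <- (-half[k]:half[k]) / fs
    w <- exp(2i * pi * freqs[k] * tt) * exp(-tt^2 / (2 * sigma_t[k]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wpad <- complex(length.out = nfft)
    wpad[seq_along(w)] <- w
    wf <- stats::fft(wpad)
    conv <- stats::mvfft(df * wf, inverse = TRUE) / nfft
    seg <- conv[half[k] + tidx, , drop = FALSE]
    p <- Mod(seg)^2
    for (i in seq_len(ntr)) {
      power[i, , k, ] <- t(p[, (i - 1) * nch + seq_len(nch), drop = FALSE])
    }
  }
  structure(list(power = power, times = epochs$times[tidx], freqs = freqs,
                 channels = channels, info = epochs$info),
            class = "bci_tfr")
}

#' Single-trial percent-change baseline normalization
#'
#' Expresses power as percent change from the mean over the baseline
#' window, separately per trial, channel and frequency.
#'
#' @param tfr A `bci_tfr`.
#' @param baseline Length-2 window in seconds (default `c(-3, -2)`, the
#'   fixation-cross interval).
#' @return A `bci_tfr` whose `power` holds percent change.
#' @export
baseline_normalize <- function(tfr, baseline = c(-3, -2)) {
  stopifnot(inherits(tfr, "bci_tfr"))
  bidx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bidx) == 0) stop_bci("baseline window outside epoch")
  base <- apply(tfr$power[, , , bidx, drop = FALSE], 1:3, mean)
  if (any(base <= 0)) stop_bci("non-positive baseline power")
  out <- tfr
  out$power <- 100 * (sweep(tfr$power, 1:3, base, "/") - 1)
  out
}

#' Average power over bands and a control window
#'
#' @param tfr A `bci_tfr` (typically baseline-normalized).
#' @param bands Named list of Hz intervals (default [band_spec()]).
#' @param window Time window in seconds (default `c(0, 5)`, the real-time
#'   control period).
#' @return Array trials x channels x bands.
#' @export
band_average <- function(tfr, bands = band_spec(), window = c(0, 5)) {
  stopifnot(inherits(tfr, "bci_tfr"))
  tidx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  out <- array(0, c(dim(tfr$power)[1], dim(tfr$power)[2], length(bands)),
               dimnames = list(NULL, tfr$channels, names(bands)))
  for (b in seq_along(bands)) {
    fidx <- which(tfr$freqs >= bands[[b]][1] & tfr$freqs <= bands[[b]][2])
    if (length(fidx) == 0) stop_bci("empty band '%s'", names(bands)[b])
    out[, , b] <- apply(tfr$power[, , fidx, tidx, drop = FALSE], 1:2, mean)
  }
  out
}

# ---- cluster machinery ----------------------------------------------------

# Connected components of `mask` channels under `adj` (both over the same
# channel set). Returns a list of integer index vectors.
connected_clusters <- function(mask, adj) {
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  sub <- adj[idx, idx, drop = FALSE]
  unseen <- rep(TRUE, length(idx))
  out <- list()
  while (any(unseen)) {
    start <- which(unseen)[1]
    comp <- start
    frontier <- start
    unseen[start] <- FALSE
    while (length(frontier)) {
      nb <- which(rowSums(sub[, frontier, drop = FALSE]) > 0 & unseen)
      comp <- c(comp, nb)
      unseen[nb] <- FALSE
      frontier <- nb
    }
    out[[length(out) + 1]] <- idx[sort(comp)]
  }
  out
}

check_connected <- function(adj) {
  n <- nrow(adj)
  comp <- connected_clusters(rep(TRUE, n), adj)
  if (length(comp) != 1) {
    stop_bci("montage adjacency is disconnected (%d components)",
             length(comp))
  }
  invisible(TRUE)
}

# Cluster statistics of a t map: suprathreshold channels grouped per sign.
cluster_stats <- function(t_map, thr, adj, stat) {
  res <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t_map > thr else t_map < -thr
    for (comp in connected_clusters(mask, adj)) {
      s <- if (stat == "size") length(comp) else sum(abs(t_map[comp]))
      res[[length(res) + 1]] <- list(channels = comp, sign = sgn,
                                     size = length(comp), stat = s)
    }
  }
  res
}

max_cluster_stat <- function(t_map, thr, adj, stat) {
  cl <- cluster_stats(t_map, thr, adj, stat)
  if (length(cl) == 0) return(0)
  max(vapply(cl, `[[`, numeric(1), "stat"))
}

# Shared tail: observed t map + a function drawing null t maps -> clusters
# with permutation p values.
cluster_permutation <- function(t_obs, null_t_fun, adj, n_perm, alpha, stat,
                                df, labels) {
  check_connected(adj)
  thr <- stats::qt(1 - alpha / 2, df)
  clusters <- cluster_stats(t_obs, thr, adj, stat)
  null_max <- vapply(seq_len(n_perm), function(p) {
    max_cluster_stat(null_t_fun(p), thr, adj, stat)
  }, numeric(1))
  for (i in seq_along(clusters)) {
    clusters[[i]]$p <- (1 + sum(null_max >= clusters[[i]]$stat)) /
      (n_perm + 1)
    clusters[[i]]$channels <- labels[clusters[[i]]$channels]
  }
  structure(list(clusters = clusters, t = stats::setNames(t_obs, labels),
                 threshold = thr, n_perm = n_perm, stat = stat,
                 alpha = alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), |t| threshold %.2f, %d permutations\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  sign %+d  size %d  stat %.2f  p = %.4g\n",
                cl$sign, cl$size, cl$stat, cl$p))
  }
  invisible(x)
}

#' Any cluster significant at a level?
#' @param result A `cluster_result`.
#' @param alpha Significance level (default 0.05).
#' @return Logical.
#' @export
any_significant_cluster <- function(result, alpha = 0.05) {
  any(vapply(result$clusters, function(cl) cl$p < alpha, logical(1)))
}

#' Cluster-based permutation test against baseline
#'
#' One-sample (paired vs baseline) sensor-space cluster test: per-channel
#' t statistic of participant-level values against zero, channels with |t|
#' above the two-tailed cluster-forming threshold grouped into
#' adjacency-connected clusters separately per sign, and each cluster's
#' statistic (size by default, summed |t| mass optionally) compared to the
#' permutation null of the maximal cluster statistic under random
#' within-participant sign flips.
#'
#' @param x Matrix participants x channels of paired differences (e.g.
#'   percent power change of control vs baseline).
#' @param adjacency Symmetric logical adjacency over the same channels
#'   (e.g. [scalp_adjacency()]).
#' @param n_perm Number of permutations (default 1000; ignored when
#'   `exact = TRUE`).
#' @param alpha Cluster-forming (and reporting) two-tailed level.
#' @param stat Cluster statistic: `"size"` (default) or `"mass"`.
#' @param seed Integer seed.
#' @param exact Enumerate all `2^n` sign-flip assignments instead of
#'   sampling them (small cohorts only); p values are then exact
#'   proportions over the full null distribution.
#' @return A `cluster_result`.
#' @export
cluster_test_baseline <- function(x, adjacency, n_perm = 1000, alpha = 0.05,
                                  stat = c("size", "mass"), seed = 1L,
                                  exact = FALSE) {
  stat <- match.arg(stat)
  n <- nrow(x)
  ss <- colSums(x^2)
  t_of <- function(m) {
    v <- (ss - n * m^2) / (n - 1)
    m / sqrt(pmax(v, 1e-300) / n)
  }
  t_obs <- t_of(colMeans(x))
  if (exact) {
    if (n > 20) stop_bci("exact enumeration limited to n <= 20 participants")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- with_seed(mix_seed(seed, 577L), {
      matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
    })
  }
  m_null <- (signs %*% x) / n
  null_t_fun <- function(p) t_of(m_null[p, ])
  res <- cluster_permutation(t_obs, null_t_fun, adjacency, nrow(signs),
                             alpha, stat, df = n - 1, labels = colnames(x))
  if (exact) {
    # exact p: proportion over the full enumeration, no +1 correction
    null_max <- vapply(seq_len(nrow(signs)), function(p) {
      max_cluster_stat(null_t_fun(p), stats::qt(1 - alpha / 2, n - 1),
                       adjacency, stat)
    }, numeric(1))
    for (i in seq_along(res$clusters)) {
      res$clusters[[i]]$p <- mean(null_max >= res$clusters[[i]]$stat)
    }
    res$exact <- TRUE
  }
  res
}

#' Cluster-based permutation test of a linear day trend
#'
#' Per channel, the planned-contrast score per participant (contrast-
#' weighted sum over days) is tested against zero across participants;
#' clustering and inference as in [cluster_test_baseline()], with the
#' permutation null built by reshuffling day labels within participants.
#'
#' @param y Array participants x channels x days.
#' @param contrast Per-day contrast weights (default [contrast_weights()]).
#' @param adjacency Channel adjacency matrix.
#' @param n_perm,alpha,stat,seed As in [cluster_test_baseline()].
#' @return A `cluster_result`.
#' @export
cluster_test_trend <- function(y, contrast = NULL, adjacency,
                               n_perm = 1000, alpha = 0.05,
                               stat = c("size", "mass"), seed = 1L) {
  stat <- match.arg(stat)
  nd <- dim(y)[3]
  np <- dim(y)[1]
  if (anyNA(y)) stop_bci("missing days in trend input")
  contrast <- contrast %||% contrast_weights(nd)
  score <- function(wmat) {
    s <- matrix(0, np, dim(y)[2])
    for (i in seq_len(np)) s[i, ] <- drop(y[i, , ] %*% wmat[i, ])
    s
  }
  tstat <- function(s) {
    m <- colMeans(s)
    v <- apply(s, 2, stats::var)
    m / sqrt(pmax(v, 1e-300) / np)
  }
  w_obs <- matrix(contrast, np, nd, byrow = TRUE)
  t_obs <- tstat(score(w_obs))
  perms <- with_seed(mix_seed(seed, 733L), {
    lapply(seq_len(n_perm), function(p) {
      t(vapply(seq_len(np), function(i) contrast[sample(nd)],
               numeric(nd)))
    })
  })
  null_t_fun <- function(p) tstat(score(perms[[p]]))
  cluster_permutation(t_obs, null_t_fun, adjacency, n_perm, alpha, stat,
                      df = np - 1, labels = dimnames(y)[[2]])
}

#' Cluster test of the power x training interaction on performance
#'
#' Per channel, models per-participant-per-day BCI performance as a
#' function of that channel's band power, the contrast-coded day, and
#' their interaction, with participant intercepts; the interaction t value
#' enters the cluster machinery, and the permutation null reshuffles day
#' labels of the power values within participants. A positive cluster
#' means the power-performance coupling strengthens with training.
#'
#' @param performance Data frame `participant`, `day`, `value`.
#' @param power Array participants x channels x days (participant order =
#'   sorted unique participants of `performance`).
#' @param adjacency Channel adjacency matrix.
#' @param contrast Per-day contrast weights.
#' @param n_perm,alpha,stat,seed As in [cluster_test_baseline()].
#' @return A `cluster_result`.
#' @export
brain_behavior_interaction <- function(performance, power, adjacency,
                                       contrast = NULL, n_perm = 1000,
                                       alpha = 0.05,
                                       stat = c("size", "mass"),
                                       seed = 1L) {
  stat <- match.arg(stat)
  parts <- sort(unique(performance$participant))
  days <- sort(unique(performance$day))
  np <- length(parts)
  nd <- length(days)
  nch <- dim(power)[2]
  if (dim(power)[1] != np || dim(power)[3] != nd) {
    stop_bci("performance and power tables have unmatched participant/day keys")
  }
  contrast <- contrast %||% contrast_weights(nd)
  perf <- matrix(NA_real_, np, nd)
  perf[cbind(match(performance$participant, parts),
             match(performance$day, days))] <- performance$value
  if (anyNA(perf)) stop_bci("incomplete performance table")
  yvec <- as.vector(t(perf))              # participant-major, day within
  dayc <- rep(contrast, np)
  pid <- rep(seq_len(np), each = nd)
  dummies <- stats::model.matrix(~ 0 + factor(pid))
  df_res <- length(yvec) - (np + 2)
  t_inter <- function(pw_mat) {
    # pw_mat: (np*nd) x nch of power values aligned with yvec
    vapply(seq_len(nch), function(ch) {
      xch <- pw_mat[, ch]
      X <- cbind(dummies, xch, dayc, xch * dayc)
      fit <- stats::lm.fit(X, yvec)
      b <- fit$coefficients
      res <- fit$residuals
      s2 <- sum(res^2) / df_res
      xtxi <- chol2inv(chol(crossprod(X)))
      b[length(b)] / sqrt(s2 * xtxi[length(b), length(b)])
    }, numeric(1))
  }
  pw_obs <- matrix(0, np * nd, nch)
  for (i in seq_len(np)) {
    pw_obs[(i - 1) * nd + seq_len(nd), ] <- t(power[i, , ])
  }
  t_obs <- t_inter(pw_obs)
  perms <- with_seed(mix_seed(seed, 911L), {
    lapply(seq_len(n_perm), function(p) {
      t(vapply(seq_len(np), function(i) sample(nd), integer(nd)))
    })
  })
  null_t_fun <- function(p) {
    ord <- perms[[p]]
    pw <- matrix(0, np * nd, nch)
    for (i in seq_len(np)) {
      pw[(i - 1) * nd + seq_len(nd), ] <- t(power[i, , ord[i, ]])
    }
    t_inter(pw)
  }
  cluster_permutation(t_obs, null_t_fun, adjacency, n_perm, alpha, stat,
                      df = df_res, labels = dimnames(power)[[2]])
}
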