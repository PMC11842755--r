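# Learning-dynamics indices: per-participant OLS learning slopes, the
# planned-contrast linear mixed model for day trends, feature-weight
# summaries (top-k sum, frequency profile, band topography), the global
# feature-change index (mean consecutive-day Euclidean distance), per-key
# permutation trend tests, and Pearson correlations.

#' Planned-contrast weights for a linear day trend
#'
#' Centered, equally spaced weights; for 5 days these are -2, -1, 0, 1, 2.
#'
#' @param n_days Number of days (default 5).
#' @return Numeric vector summing to 0.
#' @export
contrast_weights <- function(n_days = 5) {
  seq_len(n_days) - (n_days + 1) / 2
}

#' Per-participant learning slope
#'
#' Ordinary least-squares slope of per-day values on the day index.
#'
#' @param values Per-day means (one per day, no missing days).
#' @param days Day indices (default `1:length(values)`).
#' @return Slope (value units per day).
#' @export
learning_slope <- function(values, days = seq_along(values)) {
  if (anyNA(values) || !all(is.finite(values))) {
    stop_bci("missing or non-finite day values")
  }
  if (length(values) != length(days)) stop_bci("values/days length mismatch")
  dc <- days - mean(days)
  sum(dc * (values - mean(values))) / sum(dc^2)
}

#' Planned-contrast linear mixed model for a day trend
#'
#' Tests a linear increase or decrease across training days: the day factor
#' is coded with centered, equally spaced contrast weights and entered as a
#' fixed effect in a linear mixed model with a random intercept per
#' participant. Reports the Satterthwaite F test for the contrast term and
#' a likelihood-ratio p value against the intercept-only model.
#'
#' @param data Data frame with columns `participant`, `day` and the value
#'   column.
#' @param value_col Name of the response column (default `"value"`).
#' @param contrast Per-day contrast weights (default [contrast_weights()]
#'   over the observed days).
#' @return List of class `trend_result`: `F`, `df1`, `df2`, `p`
#'   (Satterthwaite), `p_lrt`, `estimate` (fixed-effect coefficient),
#'   `eta_sq` (partial), `direction`.
#' @export
planned_contrast_lmm <- function(data, value_col = "value",
                                 contrast = NULL) {
  req <- c("participant", "day", value_col)
  if (!all(req %in% names(data))) {
    stop_bci("data must have columns %s", paste(req, collapse = ", "))
  }
  if (length(unique(data$participant)) < 2) {
    stop_bci("need >= 2 participants")
  }
  y <- data[[value_col]]
  if (stats::sd(y) < 1e-12) {
    stop_bci("degenerate (constant) response; trend model not identifiable")
  }
  days <- sort(unique(data$day))
  contrast <- contrast %||% contrast_weights(length(days))
  if (length(contrast) != length(days)) {
    stop_bci("contrast length (%d) != number of days (%d)",
             length(contrast), length(days))
  }
  d <- data.frame(participant = factor(data$participant),
                  cw = contrast[match(data$day, days)], y = y)
  full <- suppressMessages(lmerTest::lmer(y ~ cw + (1 | participant),
                                          data = d, REML = FALSE))
  an <- suppressMessages(stats::anova(full))
  null <- suppressMessages(lme4::lmer(y ~ 1 + (1 | participant),
                                      data = d, REML = FALSE))
  lrt <- suppressMessages(stats::anova(null, full))
  fval <- an["cw", "F value"]
  df1 <- an["cw", "NumDF"]
  df2 <- an["cw", "DenDF"]
  structure(list(
    F = fval, df1 = df1, df2 = df2,
    p = an["cw", "Pr(>F)"],
    p_lrt = lrt[["Pr(>Chisq)"]][2],
    estimate = unname(lme4::fixef(full)["cw"]),
    eta_sq = unname(fval * df1 / (fval * df1 + df2)),
    direction = sign(unname(lme4::fixef(full)["cw"]))
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> F(%.0f, %.1f) = %.3f, p = %.4g (LRT p = %.4g), estimate = %.4g\n",
              x$df1, x$df2, x$F, x$p, x$p_lrt, x$estimate))
  invisible(x)
}

# Coerce decoder / matrix input to a weight-map matrix.
as_weight_map <- function(map) {
  if (inherits(map, "bci_decoder")) return(map$weight_map)
  if (!is.matrix(map)) stop_bci("expected a weight-map matrix or bci_decoder")
  map
}

#' Sum of the k largest feature weights
#'
#' Weights are ranked decreasingly, ties broken deterministically in
#' channel-major, frequency-ascending order, and the top `k` are summed.
#'
#' @param map Weight map (channels x frequencies, percent) or a
#'   `bci_decoder`.
#' @param k Number of top features (default 200).
#' @return Percent, in [0, 100].
#' @export
topk_weight_sum <- function(map, k = 200) {
  m <- as_weight_map(map)
  if (k <= 0) stop_bci("k must be positive")
  v <- as.vector(t(m))  # channel-major, frequency ascending
  if (k > length(v)) stop_bci("k (%d) exceeds number of features (%d)",
                              k, length(v))
  ord <- order(-v, seq_along(v))
  sum(v[ord[seq_len(k)]])
}

#' Mean weight per frequency (disregarding channels)
#' @param map Weight map or `bci_decoder`.
#' @return Named vector, one mean weight per frequency bin.
#' @export
frequency_profile <- function(map) {
  m <- as_weight_map(map)
  colMeans(m)
}

#' Mean weight per channel within a frequency band
#' @param map Weight map or `bci_decoder`.
#' @param band Length-2 interval in Hz, inclusive.
#' @return Named vector, one mean weight per channel.
#' @export
band_topography <- function(map, band) {
  m <- as_weight_map(map)
  freqs <- as.numeric(colnames(m))
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) stop_bci("empty band [%g, %g]", band[1], band[2])
  rowMeans(m[, keep, drop = FALSE])
}

#' Global feature-change index
#'
#' Mean over the four consecutive-day Euclidean distances between full
#' weight maps: zero iff the five maps are identical, and the single-number
#' summary of how much the decoder's feature space moved over training.
#'
#' @param maps List of 5 weight maps (day 1..5), matching shapes.
#' @return Non-negative scalar.
#' @export
global_change_index <- function(maps) {
  maps <- lapply(maps, as_weight_map)
  if (length(maps) != 5) stop_bci("need 5 daily weight maps")
  dims <- vapply(maps, dim, integer(2))
  if (any(dims != dims[, 1])) stop_bci("weight-map shape mismatch")
  d <- vapply(1:4, function(i) sqrt(sum((maps[[i + 1]] - maps[[i]])^2)),
              numeric(1))
  mean(d)
}

#' Per-key permutation trend test
#'
#' For each key (e.g. frequency bin or electrode), computes the
#' planned-contrast score per participant (sum of contrast-weighted per-day
#' values) and its one-sample t statistic across participants, then builds
#' a permutation null by reshuffling day labels within participants - the
#' same reshuffle applied to every key of a given permutation.
#'
#' @param data Data frame with columns `participant`, `day`, `key`,
#'   `value`; complete participant x day x key design.
#' @param contrast Per-day contrast weights.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @return Data frame: `key`, `estimate` (mean contrast score), `stat`
#'   (t), `p_perm` (two-tailed, floored at 1/(n_perm+1)), `direction`.
#' @export
trend_permutation_by_feature <- function(data, contrast = NULL,
                                         n_perm = 1000, seed = 1L) {
  req <- c("participant", "day", "key", "value")
  if (!all(req %in% names(data))) {
    stop_bci("data must have columns %s", paste(req, collapse = ", "))
  }
  parts <- sort(unique(data$participant))
  if (length(parts) < 2) stop_bci("need >= 2 participants")
  if (n_perm < 100) warning("n_perm < 100: permutation p values are coarse")
  days <- sort(unique(data$day))
  keys <- unique(data$key)
  contrast <- contrast %||% contrast_weights(length(days))
  arr <- array(NA_real_, c(length(parts), length(days), length(keys)))
  ii <- cbind(match(data$participant, parts), match(data$day, days),
              match(data$key, keys))
  arr[ii] <- data$value
  if (anyNA(arr)) stop_bci("incomplete participant x day x key design")

  score <- function(wmat) {
    # wmat: participants x days of contrast weights -> participants x keys
    v <- vapply(seq_along(parts),
                function(i) drop(wmat[i, ] %*% arr[i, , , drop = TRUE]),
                numeric(length(keys)))
    if (length(keys) == 1) matrix(v, ncol = 1) else t(v)
  }
  tstat <- function(c_mat) {
    m <- colMeans(c_mat)
    se <- apply(c_mat, 2, stats::sd) / sqrt(nrow(c_mat))
    m / pmax(se, 1e-300)
  }
  w_obs <- matrix(contrast, length(parts), length(days), byrow = TRUE)
  c_obs <- score(w_obs)
  t_obs <- tstat(c_obs)
  exceed <- numeric(length(keys))
  with_seed(mix_seed(seed, 271L), {
    for (p in seq_len(n_perm)) {
      wp <- t(vapply(seq_along(parts),
                     function(i) contrast[sample(length(days))],
                     numeric(length(days))))
      tp <- tstat(score(wp))
      exceed <- exceed + (abs(tp) >= abs(t_obs) - 1e-12)
    }
  })
  data.frame(key = keys, estimate = colMeans(c_obs), stat = t_obs,
             p_perm = (1 + exceed) / (n_perm + 1),
             direction = sign(colMeans(c_obs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation between two per-participant scalars
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r` and two-tailed `p`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_bci("need two equal-length vectors with n >= 3")
  }
  if (!all(is.finite(c(x, y)))) stop_bci("non-finite input")
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) {
    stop_bci("zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
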