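# Simulated online session: causal windows stream through the decoder; the
# battery feedback integrates the *sign of the change* in the cued-class
# probability at every update, in continuous or discontinuous display mode.

#' Run one simulated online trial
#'
#' At each update step the change in cued-class probability
#' `dp = p(t) - p(t - hop)` (first step compared against the uninformative
#' prior 0.5) moves the battery by `delta * sign(dp)`, clipped to [0, 1].
#' The trial ends when the battery is full or at the timeout. Continuous
#' mode displays the battery itself; discontinuous mode displays only its
#' increments, modelled as the running maximum (a ratcheted display).
#'
#' @param model A `bci_decoder`, or `NULL` when `p_cued` is supplied.
#' @param stream Matrix of causal per-step feature vectors (steps x
#'   features), ignored when `p_cued` is given.
#' @param cued Cued class, `"fo"` or `"gi"`.
#' @param p_cued Optional precomputed per-step cued-class probabilities.
#' @param mode `"continuous"` or `"discontinuous"` feedback display.
#' @param delta Battery step per update (default 1/250, so a uniformly
#'   favourable 5 s trial at 20 ms updates fills exactly at the timeout).
#' @param hop Update interval in seconds (default 0.02).
#' @param timeout Maximum control duration in seconds (default 5).
#' @return Object of class `feedback_trace`: data frame with `time`,
#'   `p_cued`, `decoded`, `battery`, `displayed`; attributes `cued`,
#'   `outcome` (`"filled"` or `"timeout"`), `mode`.
#' @export
run_online_trial <- function(model = NULL, stream = NULL, cued,
                             p_cued = NULL,
                             mode = c("continuous", "discontinuous"),
                             delta = 1 / 250, hop = 0.02, timeout = 5) {
  mode <- match.arg(mode)
  if (!(delta > 0 && delta <= 1)) stop_bci("delta must be in (0, 1]")
  if (is.null(p_cued)) {
    if (is.null(model) || is.null(stream) || nrow(stream) == 0) {
      stop_bci("empty stream: supply `stream` + `model`, or `p_cued`")
    }
    p_cued <- predict_proba(model, stream)[, cued]
  }
  if (length(p_cued) == 0) stop_bci("empty probability stream")
  n_max <- floor(timeout / hop + 1e-9)
  n <- min(length(p_cued), n_max)
  battery <- numeric(n)
  b <- 0
  prev <- 0.5
  last <- n
  for (t in seq_len(n)) {
    dp <- p_cued[t] - prev
    b <- min(1, max(0, b + delta * sign(dp)))
    battery[t] <- b
    prev <- p_cued[t]
    if (b >= 1 - 1e-12) {
      last <- t
      break
    }
  }
  steps <- seq_len(last)
  battery <- battery[steps]
  displayed <- if (mode == "continuous") battery else cummax(battery)
  other <- setdiff(c("fo", "gi"), cued)
  decoded <- ifelse(p_cued[steps] > 0.5, cued, other)
  trace <- data.frame(
    time = steps * hop,
    p_cued = p_cued[steps],
    decoded = decoded,
    battery = battery,
    displayed = displayed,
    stringsAsFactors = FALSE
  )
  structure(trace, class = c("feedback_trace", "data.frame"),
            cued = cued, mode = mode,
            outcome = if (battery[length(battery)] >= 1 - 1e-12) "filled"
                      else "timeout")
}

#' Per-trial BCI-control performance
#'
#' The percentage of decoder outputs matching the cued class over the
#' trial's update steps. The decoded class is the probability argmax; exact
#' ties (p = 0.5) count as non-matching.
#'
#' @param trace A `feedback_trace`.
#' @return Percentage in [0, 100].
#' @export
trial_performance <- function(trace) {
  stopifnot(inherits(trace, "feedback_trace"))
  if (nrow(trace) == 0) stop_bci("empty trace")
  100 * mean(trace$decoded == attr(trace, "cued"))
}

#' Run a full simulated online session
#'
#' Streams every trial of an online epoch set through the decoder: causal
#' 500 ms windows at the hop rate over the 5 s control period, battery
#' feedback per [run_online_trial()], and per-trial performance.
#'
#' @param model A `bci_decoder`.
#' @param epochs Online-session `epoch_set`.
#' @param config A [feature_config()] (its `hop` sets the update rate).
#' @param channels Channel selection for feature extraction (must match the
#'   model's feature index).
#' @param mode Feedback display mode.
#' @param delta Battery step per update.
#' @param timeout Control timeout in seconds.
#' @return List with `trials` (data frame: trial, class, block,
#'   performance, outcome, steps), `traces` (list of `feedback_trace`) and
#'   `mean_performance`.
#' @export
run_online_session <- function(model, epochs, config = feature_config(),
                               channels = "scalp",
                               mode = c("continuous", "discontinuous"),
                               delta = 1 / 250, timeout = 5) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "bci_decoder"), inherits(epochs, "epoch_set"))
  feats <- extract_features(epochs, config, channels = channels,
                            tmin = 0, tmax = timeout)
  if (ncol(feats$x) != length(model$weights)) {
    stop_bci("montage mismatch: session features (%d) != model features (%d)",
             ncol(feats$x), length(model$weights))
  }
  probs <- predict_proba(model, feats$x)
  info <- epochs$info
  traces <- vector("list", nrow(info))
  perf <- numeric(nrow(info))
  outcome <- character(nrow(info))
  steps <- integer(nrow(info))
  for (i in seq_len(nrow(info))) {
    rows <- feats$meta$trial == info$trial[i]
    tr <- run_online_trial(p_cued = probs[rows, info$class[i]],
                           cued = info$class[i], mode = mode,
                           delta = delta, hop = config$hop,
                           timeout = timeout)
    traces[[i]] <- tr
    perf[i] <- trial_performance(tr)
    outcome[i] <- attr(tr, "outcome")
    steps[i] <- nrow(tr)
  }
  trials <- data.frame(trial = info$trial, class = info$class,
                       block = info$block, performance = perf,
                       outcome = outcome, steps = steps,
                       stringsAsFactors = FALSE)
  list(trials = trials, traces = traces, mean_performance = mean(perf))
}

#' Write feedback traces to CSV
#' @param traces List of `feedback_trace` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    cbind(trial = i, as.data.frame(traces[[i]]),
          cued = attr(traces[[i]], "cued"),
          outcome = attr(traces[[i]], "outcome"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
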