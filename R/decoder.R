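# Two-class random-forest decoder: calibration with trial-stratified 8-fold
# cross-validation, impurity-based feature weights normalized to percent,
# probability output, and an EMG-restricted mode via restrict_to_emg().

#' Calibrate the random-forest decoder
#'
#' Fits a probability random forest on all windows and estimates held-out
#' window-level accuracy by k-fold cross-validation with folds stratified
#' at the trial level (all windows of a trial share a fold, preventing
#' leakage between overlapping windows) and balanced across classes.
#' Feature weights are impurity importances normalized to sum to 100%.
#'
#' @param features A `feature_matrix`.
#' @param labels Class per window; defaults to the labels carried in
#'   `features$meta`.
#' @param k Number of CV folds (default 8).
#' @param seed Integer seed (fold assignment and forest randomness).
#' @param num_trees Number of trees (default 500).
#' @param do_cv Compute cross-validated accuracy (default TRUE).
#' @return Object of class `bci_decoder` with elements `forest`,
#'   `feature_index`, `weights` (percent per feature), `weight_map`
#'   (channels x frequencies), `cv_accuracy` (percent, `NA` if `do_cv` is
#'   FALSE), `classes` and `meta`.
#' @export
calibrate <- function(features, labels = NULL, k = 8, seed = 1L,
                      num_trees = 500, do_cv = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$x
  labels <- labels %||% features$meta$label
  if (length(labels) != nrow(x)) stop_bci("labels length mismatch")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_bci("single-class input; need both classes")
  if (nrow(x) < k) stop_bci("fewer rows (%d) than folds (%d)", nrow(x), k)
  y <- factor(labels, levels = classes)
  trial <- features$meta$trial %||% seq_len(nrow(x))

  cv_accuracy <- NA_real_
  if (do_cv) {
    tr_tab <- unique(data.frame(trial = trial,
                                label = labels, stringsAsFactors = FALSE))
    if (nrow(tr_tab) < k) stop_bci("fewer trials (%d) than folds (%d)",
                                   nrow(tr_tab), k)
    fold <- integer(nrow(tr_tab))
    fold_of <- with_seed(mix_seed(seed, 17L), {
      pos <- 0L
      for (cl in classes) {
        i <- which(tr_tab$label == cl)
        fold[i] <- ((pos + seq_along(i) - 1L) %% k + 1L)[sample(length(i))]
        pos <- pos + length(i)
      }
      fold
    })
    fold_row <- fold_of[match(trial, tr_tab$trial)]
    acc <- vapply(seq_len(k), function(f) {
      tr <- fold_row != f
      if (all(tr) || length(unique(y[tr])) < 2) return(NA_real_)
      fit <- ranger::ranger(x = x[tr, , drop = FALSE], y = y[tr],
                            num.trees = num_trees, seed = mix_seed(seed, f),
                            num.threads = 1)
      pred <- stats::predict(fit, data = x[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
      mean(pred == y[!tr])
    }, numeric(1))
    cv_accuracy <- 100 * mean(acc, na.rm = TRUE)
  }

  forest <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                           probability = TRUE, importance = "impurity",
                           seed = mix_seed(seed, 0L), num.threads = 1)
  imp <- forest$variable.importance
  imp[!is.finite(imp) | imp < 0] <- 0
  weights <- if (sum(imp) > 0) 100 * imp / sum(imp) else
    rep(100 / length(imp), length(imp))
  names(weights) <- colnames(x)

  structure(list(forest = forest, feature_index = features$index,
                 weights = weights,
                 weight_map = weights_to_map(weights, features$index),
                 cv_accuracy = cv_accuracy, classes = classes,
                 meta = list(k = k, seed = seed, num_trees = num_trees,
                             n_windows = nrow(x))),
            class = "bci_decoder")
}

# Arrange a named weight vector as a channels x frequencies matrix in the
# canonical (channel-major, frequency-ascending) order.
weights_to_map <- function(weights, index) {
  chans <- unique(index$channel)
  freqs <- sort(unique(index$freq))
  m <- matrix(weights, nrow = length(chans), ncol = length(freqs),
              byrow = TRUE, dimnames = list(chans, freqs))
  m
}

#' @export
print.bci_decoder <- function(x, ...) {
  cat(sprintf("<bci_decoder> %d features, %d trees; CV accuracy %s\n",
              length(x$weights), x$meta$num_trees,
              if (is.na(x$cv_accuracy)) "not computed" else
                sprintf("%.1f%%", x$cv_accuracy)))
  invisible(x)
}

#' Class probabilities for feature vectors
#'
#' @param model A `bci_decoder`.
#' @param x Feature vector or matrix (rows = windows) matching the model's
#'   feature index.
#' @return Matrix rows x 2 with columns in the model's fixed class order
#'   (`fo`, `gi`); each row sums to 1.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "bci_decoder"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights)) {
    stop_bci("feature vector length %d does not match model (%d)",
             ncol(x), length(model$weights))
  }
  colnames(x) <- names(model$weights)
  p <- stats::predict(model$forest, data = x, num.threads = 1)$predictions
  p[, model$classes, drop = FALSE]
}

#' Export a weight map to CSV (channels x frequencies)
#' @param model A `bci_decoder` or a weight-map matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_map <- function(model, path) {
  m <- if (inherits(model, "bci_decoder")) model$weight_map else model
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
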