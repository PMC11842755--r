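# End-to-end cohort driver: for each participant and training day,
# simulate the offline session, preprocess, extract features, calibrate
# the decoder, simulate and run the online session, and collect the
# per-day performance and weight maps that the learning-dynamics analyses
# consume.

#' Run the full pipeline for one participant-day
#'
#' @param profile A [learner_profile()].
#' @param day Training day (1-5).
#' @param montage A [make_montage()] result.
#' @param n_per_class_offline,n_per_class_online Trials per class.
#' @param calib_config,online_config [feature_config()] objects for
#'   calibration (typically a coarser hop) and online streaming.
#' @param num_trees Forest size.
#' @param do_cv Compute calibration CV accuracy.
#' @param seed Integer seed.
#' @return List: `cv_accuracy`, `mean_performance`, `weight_map`,
#'   `trials` (online per-trial table).
#' @export
run_participant_day <- function(profile, day, montage = make_montage(16),
                                n_per_class_offline = 8,
                                n_per_class_online = 8,
                                calib_config = feature_config(hop = 0.25),
                                online_config = feature_config(hop = 0.1),
                                num_trees = 200, do_cv = FALSE,
                                seed = 1L) {
  ep_off <- simulate_epoch_set(profile, day, "offline", montage,
                               n_per_class = n_per_class_offline,
                               seed = seed)
  feats <- extract_features(ep_off, calib_config)
  model <- calibrate(feats, seed = mix_seed(seed, day),
                     num_trees = num_trees, do_cv = do_cv)
  ep_onl <- simulate_epoch_set(profile, day, "online", montage,
                               n_per_class = n_per_class_online,
                               seed = mix_seed(seed, 5L))
  sess <- run_online_session(model, ep_onl, online_config)
  list(cv_accuracy = model$cv_accuracy,
       mean_performance = sess$mean_performance,
       weight_map = model$weight_map,
       trials = sess$trials)
}

#' Run the 5-day study for a whole cohort
#'
#' Applies [run_participant_day()] to every participant and day of a
#' simulated cohort and returns the tidy per-day table plus the per-day
#' weight maps needed by the learning-dynamics analyses.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param days Training days (default 1:5).
#' @param ... Passed to [run_participant_day()].
#' @return List: `table` (data frame participant, day, learner,
#'   planted_rate, performance, cv_accuracy, topk), `weight_maps` (nested
#'   list participant -> day).
#' @export
run_cohort_study <- function(cohort, days = 1:5, ...) {
  stopifnot(inherits(cohort, "bci_cohort"))
  rows <- list()
  weight_maps <- list()
  for (i in seq_along(cohort)) {
    profile <- cohort[[i]]
    pid <- profile$participant_id
    weight_maps[[pid]] <- list()
    for (day in days) {
      res <- run_participant_day(profile, day,
                                 seed = mix_seed(attr(profile, "session_seed"),
                                                 day), ...)
      weight_maps[[pid]][[day]] <- res$weight_map
      nfeat <- length(res$weight_map)
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid, day = day,
        learner = isTRUE(attr(profile, "is_learner")),
        planted_rate = profile$learning_rate,
        performance = res$mean_performance,
        cv_accuracy = res$cv_accuracy,
        topk = topk_weight_sum(res$weight_map, k = min(200, nfeat %/% 2)),
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), weight_maps = weight_maps)
}

#' Learning-dynamics summary of a cohort study
#'
#' Computes the cohort-level planned-contrast trend on mean online
#' performance, per-participant learning slopes and their correlation with
#' the planted learning rates, and the per-participant global
#' feature-change index.
#'
#' @param study A [run_cohort_study()] result.
#' @return List: `trend` (a `trend_result`), `slopes` (data frame),
#'   `slope_rate_correlation` (list r/p), `global_index` (named vector).
#' @export
summarize_cohort_learning <- function(study) {
  tab <- study$table
  trend <- planned_contrast_lmm(
    data.frame(participant = tab$participant, day = tab$day,
               value = tab$performance))
  sp <- split(tab, tab$participant)
  slopes <- data.frame(
    participant = names(sp),
    slope = vapply(sp, function(g) learning_slope(g$performance[order(g$day)]),
                   numeric(1)),
    planted_rate = vapply(sp, function(g) g$planted_rate[1], numeric(1)),
    learner = vapply(sp, function(g) g$learner[1], logical(1)),
    stringsAsFactors = FALSE)
  corr <- correlate(slopes$slope, slopes$planted_rate)
  gidx <- vapply(study$weight_maps, function(maps) {
    if (length(maps) == 5) global_change_index(maps) else NA_real_
  }, numeric(1))
  list(trend = trend, slopes = slopes, slope_rate_correlation = corr,
       global_index = gidx)
}
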