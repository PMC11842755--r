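# Mental chronometry: deviation-from-isochrony index, its per-day trend
# (planned-contrast mixed model) and per-participant slopes.

#' Deviation from isochrony
#'
#' `abs(1 - imagine / speak)`: zero when imagined and overt repetitions of
#' the syllable sequence take equal time (temporally faithful imagery),
#' growing with the mismatch. Scale-invariant in the common duration unit.
#'
#' @param imagine Mean imagined-repetition duration (s).
#' @param speak Mean spoken-repetition duration (s, > 0).
#' @return Non-negative index (vectorized).
#' @export
deviation_from_isochrony <- function(imagine, speak) {
  if (any(speak <= 0)) stop_bci("speak duration must be > 0")
  abs(1 - imagine / speak)
}

#' Per-participant, per-day isochrony table
#'
#' Pools syllables within each modality, takes day-mean durations, and
#' applies [deviation_from_isochrony()] to the modality means.
#'
#' @param records Data frame with `participant`, `day`, `modality`
#'   (imagine/speak), `duration`; a `syllable` column is pooled over.
#' @return Data frame `participant`, `day`, `index`.
#' @export
isochrony_table <- function(records) {
  agg <- stats::aggregate(duration ~ participant + day + modality,
                          data = records, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("participant", "day"),
                         timevar = "modality", direction = "wide")
  data.frame(participant = wide$participant, day = wide$day,
             index = deviation_from_isochrony(wide$duration.imagine,
                                              wide$duration.speak),
             stringsAsFactors = FALSE)
}

#' Chronometry trend analysis
#'
#' Fits a linear mixed model for repetition duration with the
#' contrast-coded day, modality and (when present) group as fixed factors
#' and a participant random intercept; applies the same planned-contrast
#' machinery to the per-day deviation-from-isochrony index; and extracts
#' per-participant index slopes via [learning_slope()].
#'
#' @param records Data frame `participant`, `day`, `modality`, `syllable`,
#'   `duration`, optionally `group`.
#' @param contrast Per-day contrast weights.
#' @return List with `duration_anova` (mixed-model ANOVA table),
#'   `index_trend` (a `trend_result`), `index_slopes` (data frame
#'   participant/slope).
#' @export
chronometry_trends <- function(records, contrast = NULL) {
  req <- c("participant", "day", "modality", "duration")
  if (!all(req %in% names(records))) {
    stop_bci("records must have columns %s", paste(req, collapse = ", "))
  }
  cells <- table(records$participant, records$day, records$modality)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop_bci("missing cell: participant %s, day %s, modality %s",
             dimnames(cells)[[1]][bad[1]], dimnames(cells)[[2]][bad[2]],
             dimnames(cells)[[3]][bad[3]])
  }
  days <- sort(unique(records$day))
  contrast <- contrast %||% contrast_weights(length(days))
  d <- records
  d$cw <- contrast[match(d$day, days)]
  d$participant <- factor(d$participant)
  d$modality <- factor(d$modality)
  has_group <- "group" %in% names(d) && length(unique(d$group)) > 1
  form <- if (has_group) {
    duration ~ cw * modality * factor(group) + (1 | participant)
  } else {
    duration ~ cw * modality + (1 | participant)
  }
  fit <- suppressMessages(lmerTest::lmer(form, data = d, REML = FALSE))
  duration_anova <- suppressMessages(stats::anova(fit))

  iso <- isochrony_table(records)
  index_trend <- planned_contrast_lmm(
    data.frame(participant = iso$participant, day = iso$day,
               value = iso$index),
    contrast = contrast)
  slopes <- vapply(split(iso, iso$participant), function(g) {
    g <- g[order(g$day), ]
    learning_slope(g$index, g$day)
  }, numeric(1))
  list(duration_anova = duration_anova, index_trend = index_trend,
       index_slopes = data.frame(participant = names(slopes),
                                 slope = unname(slopes),
                                 stringsAsFactors = FALSE))
}
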