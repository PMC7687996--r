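#' Labeling configuration
#'
#' Positive rows are the feature rows ending in the `positive_horizon_min`
#' minutes immediately before a stay's first hypotension onset. Negative
#' rows come from two sources: (a) in event stays, a matching-length block
#' ending `negative_gap_min + positive_horizon_min` minutes before the
#' onset, and (b) in event-free stays, the block before a pseudo-onset
#' drawn within `pseudo_onset_jitter_min` minutes of the training
#' hypotension group's mean time-to-first-onset. Rows between the blocks
#' are unlabeled: excluded from training but retained for trajectory
#' scoring.
#'
#' @param positive_horizon_min positive-label horizon, minutes (default 15).
#' @param negative_gap_min minutes separating the event-stay negative block
#'   from the positive horizon (default 120; must exceed the horizon).
#' @param pseudo_onset_jitter_min half-width of the uniform jitter around
#'   the mean onset for pseudo-onsets (default 15).
#' @param include_event_stay_negatives include source (a) (default `TRUE`).
#' @return List of class `label_config`.
#' @export
label_config <- function(positive_horizon_min = 15L, negative_gap_min = 120L,
                         pseudo_onset_jitter_min = 15L,
                         include_event_stay_negatives = TRUE) {
  if (positive_horizon_min <= 0 || negative_gap_min <= 0 ||
      pseudo_onset_jitter_min < 0)
    stop("label horizons must be positive")
  if (negative_gap_min <= positive_horizon_min)
    stop("negative_gap_min must exceed positive_horizon_min")
  structure(list(positive_horizon_min = as.integer(positive_horizon_min),
                 negative_gap_min = as.integer(negative_gap_min),
                 pseudo_onset_jitter_min = as.integer(pseudo_onset_jitter_min),
                 include_event_stay_negatives = include_event_stay_negatives),
            class = "label_config")
}

labeled_rows <- function(features, ends, label, onset) {
  hit <- features$end_minute %in% ends
  data.frame(stay_id = features$stay_id[hit],
             end_minute = features$end_minute[hit],
             label = rep(label, sum(hit)),
             lead_time_min = onset - features$end_minute[hit],
             stringsAsFactors = FALSE)
}

#' Label feature rows of a hypotension stay
#'
#' Rows ending in `[onset - horizon, onset - 1]` are positive. When
#' event-stay negatives are enabled, rows ending in the matching-length
#' block `[onset - gap - 2h, onset - gap - h - 1]` (h = horizon, gap =
#' `negative_gap_min`) are negative. All other rows are unlabeled;
#' post-onset rows are never used for first-event training.
#'
#' @param features feature rows of one stay ([build_feature_matrix()]).
#' @param first_event_onset onset minute of the stay's first event.
#' @param config a [label_config()].
#' @return Data frame `stay_id, end_minute, label, lead_time_min` for the
#'   labeled rows only.
#' @export
label_hypotension_stay <- function(features, first_event_onset,
                                   config = label_config()) {
  h <- config$positive_horizon_min
  g <- config$negative_gap_min
  onset <- first_event_onset
  pos <- labeled_rows(features, (onset - h):(onset - 1L), "positive", onset)
  out <- pos
  if (config$include_event_stay_negatives) {
    neg_ends <- (onset - g - 2L * h):(onset - g - h - 1L)
    neg_ends <- neg_ends[neg_ends >= 0]
    if (length(neg_ends) > 0)
      out <- rbind(out, labeled_rows(features, neg_ends, "negative", onset))
  }
  if (nrow(pos) == 0)
    warning("stay ", features$stay_id[1] %||% "?",
            ": no feature rows inside the positive horizon")
  out[order(out$end_minute), ]
}

#' Label feature rows of a non-hypotension stay
#'
#' Draws a pseudo-onset uniformly within `pseudo_onset_jitter_min` minutes
#' of `mean_onset_min` (the mean time-to-first-onset of the TRAINING
#' hypotension subjects), and labels the rows ending in the
#' `positive_horizon_min` minutes before it as negative. A stay too short
#' to reach its pseudo-onset is skipped with a warning.
#'
#' @param features feature rows of one stay.
#' @param mean_onset_min mean first-onset minute from the training split.
#' @param config a [label_config()].
#' @param pseudo_onset optional explicit pseudo-onset minute; when `NULL`
#'   (default) one is drawn from the current RNG state (seed upstream for
#'   reproducibility).
#' @return List with `rows` (as in [label_hypotension_stay()]) and
#'   `pseudo_onset` (the minute used, `NA` if the stay was skipped).
#' @export
label_nonhypotension_stay <- function(features, mean_onset_min,
                                      config = label_config(),
                                      pseudo_onset = NULL) {
  j <- config$pseudo_onset_jitter_min
  if (is.null(pseudo_onset))
    pseudo_onset <- as.integer(round(runif(1, mean_onset_min - j,
                                           mean_onset_min + j)))
  h <- config$positive_horizon_min
  if (nrow(features) == 0 || max(features$end_minute) < pseudo_onset - 1L) {
    warning("stay ", features$stay_id[1] %||% "?",
            " too short for pseudo-onset ", pseudo_onset, "; skipped")
    return(list(rows = labeled_rows(features, integer(0), "negative", pseudo_onset),
                pseudo_onset = NA_integer_))
  }
  rows <- labeled_rows(features, (pseudo_onset - h):(pseudo_onset - 1L),
                       "negative", pseudo_onset)
  list(rows = rows, pseudo_onset = pseudo_onset)
}

#' Deterministic per-stay pseudo-onset draw
#'
#' The pseudo-onset of a non-hypotension stay is drawn uniformly in
#' `mean_onset_min` plus or minus the configured jitter, from a RNG stream
#' keyed on the stay id and `seed`, so the draw is reproducible and
#' independent of evaluation order.
#'
#' @inheritParams label_nonhypotension_stay
#' @param stay_id the stay identifier.
#' @param seed integer base seed.
#' @return Integer pseudo-onset minute.
#' @export
pseudo_onset_for <- function(stay_id, mean_onset_min,
                             config = label_config(), seed = 1L) {
  set.seed((as.integer(seed) + sum(utf8ToInt(as.character(stay_id)))) %%
             .Machine$integer.max)
  j <- config$pseudo_onset_jitter_min
  as.integer(round(runif(1, mean_onset_min - j, mean_onset_min + j)))
}

#' Chronological train/validation split by median admission date
#'
#' Subjects admitted at or before the median admission datetime (over all
#' subjects) form the training set; subjects admitted later form the
#' validation set. The split is by subject, so no subject appears on both
#' sides. All-identical admission datetimes leave the validation side
#' empty, which is an error (jitter the admissions).
#'
#' @param subjects data frame with `subject_id` and `admission_datetime`.
#' @return List with character vectors `train` and `validation` of subject
#'   ids, and `median_admission`.
#' @export
chronological_split <- function(subjects) {
  subjects <- unique(subjects[, c("subject_id", "admission_datetime")])
  if (nrow(subjects) < 2) stop("need at least 2 subjects to split")
  adm <- as.numeric(as.POSIXct(subjects$admission_datetime, tz = "UTC"))
  med <- median(adm)
  train <- subjects$subject_id[adm <= med]
  validation <- subjects$subject_id[adm > med]
  if (length(validation) == 0)
    stop("degenerate split: all admissions at or before the median; ",
         "jitter the admission datetimes")
  list(train = sort(train), validation = sort(validation),
       median_admission = as.POSIXct(med, origin = "1970-01-01", tz = "UTC"))
}

#' Label a whole cohort
#'
#' Computes the mean time-to-first-onset over the TRAINING hypotension
#' subjects only, then labels every stay: hypotension stays via
#' [label_hypotension_stay()], non-hypotension stays via
#' [label_nonhypotension_stay()] with per-stay seeded pseudo-onsets.
#' Excluded subjects are not labeled.
#'
#' @param features_by_stay named list of feature data frames, one per stay
#'   (names are stay ids).
#' @param assignments output of [classify_subjects()].
#' @param stays data frame `subject_id, stay_id` mapping subjects to their
#'   stays.
#' @param split output of [chronological_split()].
#' @param config a [label_config()].
#' @param seed integer seed for the pseudo-onset draws (each non-event stay
#'   gets its own deterministic draw).
#' @return List with `labels` (row-bound labeled rows plus `subject_id` and
#'   `split` columns), `pseudo_onsets` (data frame `stay_id, pseudo_onset`),
#'   and `mean_onset_min`.
#' @export
label_cohort <- function(features_by_stay, assignments, stays, split,
                         config = label_config(), seed = 1L) {
  hyp <- assignments[assignments$group == "hypotension", ]
  train_hyp <- hyp[hyp$subject_id %in% split$train, ]
  if (nrow(train_hyp) == 0)
    stop("no training-split hypotension subjects: cannot anchor pseudo-onsets")
  mean_onset <- mean(train_hyp$first_onset_min)
  all_rows <- list()
  pseudo <- list()
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (a$group == "excluded") next
    if (a$group == "hypotension") {
      f <- features_by_stay[[a$first_stay_id]]
      if (is.null(f)) next
      rows <- label_hypotension_stay(f, a$first_onset_min, config)
    } else {
      subject_stays <- stays$stay_id[stays$subject_id == a$subject_id]
      subject_stays <- intersect(subject_stays, names(features_by_stay))
      if (length(subject_stays) == 0) next
      res_all <- lapply(subject_stays, function(st) {
        r <- label_nonhypotension_stay(
          features_by_stay[[st]], mean_onset, config,
          pseudo_onset = pseudo_onset_for(st, mean_onset, config, seed))
        pseudo[[st]] <<- r$pseudo_onset
        r$rows
      })
      rows <- do.call(rbind, res_all)
    }
    if (nrow(rows) > 0) {
      rows$subject_id <- a$subject_id
      rows$split <- if (a$subject_id %in% split$train) "train" else "validation"
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  labels <- do.call(rbind, all_rows)
  rownames(labels) <- NULL
  pseudo_df <- data.frame(stay_id = names(pseudo),
                          pseudo_onset = unlist(pseudo),
                          stringsAsFactors = FALSE)
  rownames(pseudo_df) <- NULL
  list(labels = labels, pseudo_onsets = pseudo_df, mean_onset_min = mean_onset)
}
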