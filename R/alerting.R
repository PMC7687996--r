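#' Alert policy
#'
#' An alert candidate is any minute whose alert score meets or exceeds
#' `threshold` (inclusive); emitted alerts are then thinned greedily so
#' that no alert is generated within `lockout_min` minutes after the
#' previously EMITTED alert.
#'
#' @param threshold score cutoff in \[0, 1\] (default 0.5).
#' @param lockout_min lockout period in minutes (default 15).
#' @return List of class `alert_policy`.
#' @export
alert_policy <- function(threshold = 0.5, lockout_min = 15L) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (lockout_min < 0) stop("lockout_min must be >= 0")
  structure(list(threshold = threshold, lockout_min = as.integer(lockout_min)),
            class = "alert_policy")
}

#' Second-stage (stacked) feature rows from first-stage risk scores
#'
#' For each minute of each stay, the time since admission plus the mean,
#' minimum, maximum and standard deviation of the first-stage risk scores
#' over the trailing 5, 10 and 30 minute lookback windows (current minute
#' inclusive). A row is emitted only where all three lookback windows
#' contain at least one score; the standard deviation of a single score is
#' 0. Rows use only past and current scores, so the construction is causal.
#'
#' @param scores data frame `stay_id, minute, score` of first-stage risk
#'   scores.
#' @param lookbacks lookback window lengths in minutes (default 5, 10, 30).
#' @return Data frame `stay_id, minute, time_since_admission` plus
#'   `lb<w>_mean, lb<w>_min, lb<w>_max, lb<w>_sd` per lookback `w`.
#' @export
build_stacked_features <- function(scores, lookbacks = c(5L, 10L, 30L)) {
  out <- lapply(split(scores, scores$stay_id), function(d) {
    lo <- min(d$minute)
    hi <- max(d$minute)
    dense <- rep(NA_real_, hi - lo + 1L)
    dense[d$minute - lo + 1L] <- d$score
    blocks <- list()
    counts <- NULL
    for (w in lookbacks) {
      # pad so windows that begin before the first score still evaluate
      x <- c(rep(NA_real_, w - 1L), dense)
      m <- cpp_roll_features(x, as.integer(w), 1L, 1.0, 1e-12)
      m <- m[w:length(x), , drop = FALSE]
      n_present <- m[, ncol(m)]
      sd_col <- ifelse(n_present == 1, 0, sqrt(m[, 2]))
      b <- cbind(m[, 1], m[, 3], m[, 4], sd_col)
      colnames(b) <- paste0("lb", w, c("_mean", "_min", "_max", "_sd"))
      blocks[[length(blocks) + 1L]] <- b
      counts <- if (is.null(counts)) n_present >= 1 else counts & n_present >= 1
    }
    mat <- do.call(cbind, blocks)
    keep <- counts & stats::complete.cases(mat)
    minutes <- lo:hi
    cbind(data.frame(stay_id = d$stay_id[1],
                     minute = minutes[keep],
                     time_since_admission = minutes[keep],
                     stringsAsFactors = FALSE),
          as.data.frame(mat[keep, , drop = FALSE]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train the stacked second-stage alert model
#'
#' Fits a classifier (random forest by default) on the stacked features at
#' labeled minutes, under the same subject-level cross-validation contract
#' as the first-stage model. Its output is an alert score in \[0, 1\].
#'
#' @param stacked data frame from [build_stacked_features()].
#' @param labels data frame `stay_id, end_minute, label, subject_id`
#'   ([label_cohort()] rows); joined on `(stay_id, minute)`.
#' @param spec a [model_spec()] (default random forest).
#' @param k folds (default 10).
#' @return A `hypo_cv` object (see [cross_validate()]).
#' @export
train_stacked <- function(stacked, labels, spec = model_spec("random_forest"),
                          k = 10L) {
  key_s <- paste(stacked$stay_id, stacked$minute)
  key_l <- paste(labels$stay_id, labels$end_minute)
  hit <- match(key_s, key_l)
  use <- !is.na(hit)
  if (!any(use)) stop("no stacked rows coincide with labeled minutes")
  x <- as.matrix(stacked[use, setdiff(names(stacked), c("stay_id", "minute")),
                         drop = FALSE])
  y <- as.integer(labels$label[hit[use]] == "positive")
  subj <- labels$subject_id[hit[use]]
  cross_validate(x, y, subj, spec, k = k)
}

#' Score stacked rows with a trained second-stage model
#'
#' @param cv a `hypo_cv` (or `hypo_risk_model`) from [train_stacked()].
#' @param stacked data frame from [build_stacked_features()].
#' @return Data frame `stay_id, minute, score`.
#' @export
score_stacked <- function(cv, stacked) {
  model <- if (inherits(cv, "hypo_cv")) cv$model else cv
  x <- as.matrix(stacked[, setdiff(names(stacked), c("stay_id", "minute")),
                         drop = FALSE])
  data.frame(stay_id = stacked$stay_id, minute = stacked$minute,
             score = predict_risk(model, x), stringsAsFactors = FALSE)
}

#' Candidate alert minutes: threshold exceedances
#'
#' Minutes whose score meets or exceeds the threshold (inclusive), in
#' increasing order.
#'
#' @param scores data frame `minute, score` for one stay.
#' @param threshold score cutoff.
#' @return Integer vector of minutes.
#' @export
raw_exceedances <- function(scores, threshold) {
  sort(scores$minute[!is.na(scores$score) & scores$score >= threshold])
}

#' Apply an alert lockout
#'
#' Greedy left-to-right thinning: a candidate is emitted iff more than
#' `lockout_min` minutes have elapsed since the previously EMITTED alert.
#' Idempotent; with `lockout_min = 0` all candidates are emitted.
#'
#' @param candidate_minutes sorted integer vector of candidate minutes.
#' @param lockout_min lockout period in minutes.
#' @return Integer vector of emitted alert minutes.
#' @export
apply_lockout <- function(candidate_minutes, lockout_min) {
  if (length(candidate_minutes) == 0) return(integer(0))
  emitted <- candidate_minutes[1]
  last <- emitted
  for (m in candidate_minutes[-1]) {
    if (m - last > lockout_min) {
      emitted <- c(emitted, m)
      last <- m
    }
  }
  emitted
}

#' Emit alerts for every stay under a policy
#'
#' @param scores data frame `stay_id, minute, score` (first- or
#'   second-stage).
#' @param policy an [alert_policy()].
#' @return Data frame `stay_id, minute, score` of emitted alerts.
#' @export
emit_alerts <- function(scores, policy = alert_policy()) {
  if (nrow(scores) == 0)
    return(data.frame(stay_id = character(0), minute = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  out <- lapply(split(scores, scores$stay_id), function(d) {
    cand <- raw_exceedances(d, policy$threshold)
    em <- apply_lockout(cand, policy$lockout_min)
    data.frame(stay_id = rep(d$stay_id[1], length(em)), minute = em,
               score = d$score[match(em, d$minute)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adjudicate alerts and summarize operational performance
#'
#' An alert is a true positive iff its stay has a first hypotension event
#' with onset strictly after the alert minute (within `max_horizon_min`
#' when finite); every alert in an event-free stay is a false positive.
#' Reports the alert burden (alerts per subject-hour of monitored, i.e.
#' scored, time), the alert-level positive predictive value, the fraction
#' of hypotension subjects with at least one true-positive alert before
#' onset (sensitivity), and the complementary miss rate.
#'
#' @param alerts data frame `stay_id, minute` of emitted alerts.
#' @param onsets data frame `stay_id, onset_min` (`NA` onset = event-free
#'   stay), one row per monitored stay.
#' @param monitored_minutes data frame `stay_id, minutes` giving each
#'   stay's count of scored (monitored) minutes.
#' @param max_horizon_min how long before the event an alert still counts
#'   as true (default `Inf`: any pre-onset alert counts).
#' @return List of class `operational_metrics`: `n_alerts,
#'   alerts_per_subject_hour, alert_level_ppv, subject_sensitivity,
#'   subject_miss_rate, alerts` (adjudicated table).
#' @export
adjudicate_and_summarize <- function(alerts, onsets, monitored_minutes,
                                     max_horizon_min = Inf) {
  total_min <- sum(monitored_minutes$minutes)
  if (total_min <= 0) stop("zero monitored subject-hours")
  onset_of <- setNames(onsets$onset_min, onsets$stay_id)
  if (nrow(alerts) > 0) {
    o <- onset_of[alerts$stay_id]
    gap <- o - alerts$minute
    alerts$truth <- ifelse(!is.na(o) & gap > 0 & gap <= max_horizon_min,
                           "true-positive", "false-positive")
  } else {
    alerts$truth <- character(0)
  }
  hyp_stays <- onsets$stay_id[!is.na(onsets$onset_min)]
  hit_stays <- unique(alerts$stay_id[alerts$truth == "true-positive"])
  sens <- if (length(hyp_stays) > 0) mean(hyp_stays %in% hit_stays) else NA_real_
  structure(list(
    n_alerts = nrow(alerts),
    alerts_per_subject_hour = nrow(alerts) / (total_min / 60),
    alert_level_ppv = if (nrow(alerts) > 0)
      mean(alerts$truth == "true-positive") else NA_real_,
    subject_sensitivity = sens,
    subject_miss_rate = if (is.na(sens)) NA_real_ else 1 - sens,
    alerts = alerts), class = "operational_metrics")
}

#' Threshold sweep of the alert system
#'
#' Sweeps alert thresholds and reports, per threshold, the detected
#' fraction of hypotension subjects and the alert-level PPV under the
#' given lockout — the detected-fraction-versus-PPV operating curve.
#'
#' @param scores data frame `stay_id, minute, score`.
#' @param onsets,monitored_minutes as in [adjudicate_and_summarize()].
#' @param thresholds numeric vector of score cutoffs.
#' @param lockout_min lockout period (default 15).
#' @return Data frame `threshold, n_alerts, alerts_per_subject_hour,
#'   alert_level_ppv, subject_sensitivity`.
#' @export
threshold_sweep <- function(scores, onsets, monitored_minutes,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            lockout_min = 15L) {
  rows <- lapply(thresholds, function(th) {
    al <- emit_alerts(scores, alert_policy(th, lockout_min))
    m <- adjudicate_and_summarize(al, onsets, monitored_minutes)
    data.frame(threshold = th, n_alerts = m$n_alerts,
               alerts_per_subject_hour = m$alerts_per_subject_hour,
               alert_level_ppv = m$alert_level_ppv,
               subject_sensitivity = m$subject_sensitivity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
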