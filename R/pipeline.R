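#' Run the full hypotension-forecasting pipeline on a synthetic cohort
#'
#' Generates a cohort, cleans and imputes it, detects hypotension events,
#' classifies and chronologically splits the subjects, engineers rolling
#' features, labels them, cross-validates the requested classifier
#' families on the training split, selects a model by calibration among
#' equivalent discriminators, scores the validation stays every minute
#' over the `score_window_min` minutes preceding each stay's onset (or
#' pseudo-onset), builds event-aligned trajectories and lead-time curves,
#' trains the stacked second-stage alert model on out-of-fold first-stage
#' scores of the training stays, and evaluates the alert system with and
#' without the stacked stage and lockout.
#'
#' Fully deterministic given `config$seed` and `seed`.
#'
#' @param config a [sim_config()].
#' @param families model families to compare (default all four).
#' @param label_cfg a [label_config()].
#' @param feat_cfg a [feature_config()].
#' @param policy an [alert_policy()].
#' @param k cross-validation folds (default 10).
#' @param score_window_min minutes before each stay's origin that are
#'   scored (default 480).
#' @param trajectory_grid lead-time grid for trajectory summaries and
#'   lead-time curves.
#' @param seed integer seed governing labeling and model fits.
#' @param out_dir optional directory; when given, deterministic CSV/JSON
#'   outputs are written there.
#' @return List with the cohort, assignments, split, labels, cv results,
#'   chosen model, validation scores, trajectories and summaries,
#'   lead-time curves, calibration, alerting results, and patient-level
#'   AUPRCs.
#' @export
run_pipeline <- function(config = sim_config(),
                         families = c("random_forest", "knn",
                                      "gradient_boosting", "logistic_l2"),
                         label_cfg = label_config(),
                         feat_cfg = feature_config(),
                         policy = alert_policy(),
                         k = 10L,
                         score_window_min = 480L,
                         trajectory_grid = seq(0, 240, by = 5),
                         seed = 1L,
                         out_dir = NULL) {
  cohort <- generate_cohort(config)
  clean <- lapply(cohort$series, function(s) preprocess_series(s)$series)

  events <- do.call(rbind, lapply(clean, detect_hypotension_events))
  subjects <- data.frame(subject_id = cohort$truth$subject_id,
                         stay_id = cohort$truth$stay_id,
                         admission_datetime = cohort$truth$admission_datetime,
                         stringsAsFactors = FALSE)
  assignments <- classify_subjects(subjects, events, cohort$interventions)
  split <- chronological_split(subjects)

  hyp <- assignments[assignments$group == "hypotension", ]
  train_hyp <- hyp[hyp$subject_id %in% split$train, ]
  if (nrow(train_hyp) == 0)
    stop("no training-split hypotension subjects; enlarge the cohort")
  mean_onset <- mean(train_hyp$first_onset_min)

  # per-stay origin: first-event onset, or the seeded pseudo-onset
  origin_of <- setNames(rep(NA_integer_, nrow(subjects)), subjects$stay_id)
  origin_of[hyp$first_stay_id] <- hyp$first_onset_min
  for (st in subjects$stay_id[subjects$subject_id %in%
                              assignments$subject_id[assignments$group == "non-hypotension"]])
    origin_of[st] <- pseudo_onset_for(st, mean_onset, label_cfg, seed)

  # feature rows are only needed on the scored span before each origin
  kept_stays <- names(origin_of)[!is.na(origin_of)]
  features_by_stay <- list()
  for (st in kept_stays) {
    o <- origin_of[[st]]
    span <- max(0L, o - score_window_min):(o - 1L)
    features_by_stay[[st]] <- build_feature_matrix(clean[[st]], feat_cfg,
                                                   minutes = span)
  }

  lab <- label_cohort(features_by_stay, assignments, subjects, split,
                      label_cfg, seed = seed)
  labels <- lab$labels

  subj_of_stay <- setNames(subjects$subject_id, subjects$stay_id)
  all_features <- do.call(rbind, features_by_stay)
  rownames(all_features) <- NULL
  feat_cols <- feature_columns(all_features)

  train_lab <- labels[labels$split == "train", ]
  key_f <- paste(all_features$stay_id, all_features$end_minute)
  tr_idx <- match(paste(train_lab$stay_id, train_lab$end_minute), key_f)
  x_train <- as.matrix(all_features[tr_idx, feat_cols, drop = FALSE])
  y_train <- as.integer(train_lab$label == "positive")

  cv_results <- lapply(families, function(fam) {
    cross_validate(x_train, y_train, train_lab$subject_id,
                   model_spec(fam, seed = seed), k = k)
  })
  names(cv_results) <- families
  # re-run CV for the winner keeping the fold models, so the stacked stage
  # can be trained on out-of-fold first-stage scores
  chosen <- cross_validate(x_train, y_train, train_lab$subject_id,
                           select_model(cv_results)$spec, k = k,
                           keep_fold_models = TRUE)

  # ---- validation scoring (first stage) ----
  val_stays <- subjects$stay_id[subjects$subject_id %in% split$validation]
  val_stays <- intersect(val_stays, kept_stays)
  val_feat <- all_features[all_features$stay_id %in% val_stays, , drop = FALSE]
  scores_val <- score_minutes(chosen$model, val_feat)

  # out-of-fold first-stage scores for the TRAINING stays (stacked input)
  train_stays <- subjects$stay_id[subjects$subject_id %in% split$train]
  train_stays <- intersect(train_stays, kept_stays)
  scores_train <- do.call(rbind, lapply(train_stays, function(st) {
    f <- all_features[all_features$stay_id == st, , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    fold <- chosen$fold_of[[subj_of_stay[[st]]]]
    m <- if (!is.null(fold) && !is.na(fold)) chosen$fold_models[[fold]]
         else chosen$model
    score_minutes(m, f)
  }))
  rownames(scores_train) <- NULL

  # ---- trajectories and lead-time evaluation (validation) ----
  group_of <- setNames(ifelse(assignments$group == "hypotension",
                              "hypotension", "non-hypotension"),
                       assignments$subject_id)
  origins <- data.frame(stay_id = val_stays,
                        origin_min = unname(origin_of[val_stays]),
                        group = unname(group_of[subj_of_stay[val_stays]]),
                        stringsAsFactors = FALSE)
  trajectories <- build_trajectories(scores_val, origins)
  traj_summary <- group_summary(trajectories, trajectory_grid)
  lt_curves <- lead_time_curves(trajectories, trajectory_grid)

  val_lab <- labels[labels$split == "validation", ]
  va_idx <- match(paste(val_lab$stay_id, val_lab$end_minute), key_f)
  x_val <- as.matrix(all_features[va_idx, feat_cols, drop = FALSE])
  p_val <- predict_risk(chosen$model, x_val)
  y_val <- as.integer(val_lab$label == "positive")
  calib <- calibration(p_val, y_val)

  # ---- alerting ----
  stacked_train <- build_stacked_features(scores_train)
  stacked_cv <- train_stacked(stacked_train, labels,
                              model_spec("random_forest", seed = seed), k = k)
  stacked_val <- build_stacked_features(scores_val)
  stacked_scores <- score_stacked(stacked_cv, stacked_val)

  onsets <- data.frame(stay_id = origins$stay_id,
                       onset_min = ifelse(origins$group == "hypotension",
                                          origins$origin_min, NA_integer_))
  monitored <- aggregate(minute ~ stay_id, scores_val, length)
  names(monitored)[2] <- "minutes"

  no_lockout <- alert_policy(policy$threshold, 0L)
  alert_eval <- list(
    single = adjudicate_and_summarize(
      emit_alerts(scores_val, policy), onsets, monitored),
    single_no_lockout = adjudicate_and_summarize(
      emit_alerts(scores_val, no_lockout), onsets, monitored),
    stacked = adjudicate_and_summarize(
      emit_alerts(stacked_scores, policy), onsets, monitored),
    stacked_no_lockout = adjudicate_and_summarize(
      emit_alerts(stacked_scores, no_lockout), onsets, monitored))
  sweep <- threshold_sweep(stacked_scores, onsets, monitored,
                           lockout_min = policy$lockout_min)

  pl_auprc <- list(
    whole_stay = patient_level_auprc(scores_val, data.frame(
      stay_id = origins$stay_id, group = origins$group), "whole-stay"),
    random_hour = patient_level_auprc(scores_val, data.frame(
      stay_id = origins$stay_id, group = origins$group), "random-hour",
      seed = seed))

  result <- list(config = config, seed = seed,
                 truth = cohort$truth, events = events,
                 assignments = assignments, split = split,
                 mean_onset_min = lab$mean_onset_min,
                 pseudo_onsets = lab$pseudo_onsets,
                 labels = labels, cv_results = cv_results, chosen = chosen,
                 scores_validation = scores_val,
                 scores_train = scores_train,
                 origins = origins, trajectories = trajectories,
                 trajectory_summary = traj_summary,
                 lead_time_curves = lt_curves,
                 calibration = calib,
                 stacked_cv = stacked_cv,
                 stacked_scores = stacked_scores,
                 alert_eval = alert_eval, threshold_sweep = sweep,
                 patient_level_auprc = pl_auprc,
                 time_to_first_event = time_to_first_event_stats(assignments))
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write the pipeline's deterministic outputs
#'
#' Writes `events.csv`, `assignments.csv`, `labels.csv`, `scores.csv`,
#' `trajectory_summary.csv`, `lead_time_curves.csv`, `alerts.csv` and
#' `metrics.json` under `dir`. Rerunning the pipeline with identical
#' config and seeds reproduces these files byte for byte.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  paths <- c(
    w(result$events, "events.csv"),
    w(result$assignments, "assignments.csv"),
    w(result$labels, "labels.csv"),
    w(result$scores_validation, "scores.csv"),
    w(result$trajectory_summary, "trajectory_summary.csv"),
    w(result$lead_time_curves, "lead_time_curves.csv"),
    w(result$alert_eval$stacked$alerts, "alerts.csv"))
  metrics <- list(
    chosen_family = result$chosen$spec$family,
    cv = lapply(result$cv_results, function(r)
      list(auroc = r$mean_auroc, auprc = r$mean_auprc, brier = r$mean_brier)),
    brier_validation = result$calibration$brier,
    alerts_per_subject_hour = vapply(result$alert_eval, function(m)
      m$alerts_per_subject_hour, numeric(1)),
    alert_level_ppv = vapply(result$alert_eval, function(m)
      m$alert_level_ppv, numeric(1)),
    subject_sensitivity = vapply(result$alert_eval, function(m)
      m$subject_sensitivity, numeric(1)),
    patient_level_auprc = result$patient_level_auprc)
  mpath <- file.path(dir, "metrics.json")
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), mpath)
  invisible(c(paths, mpath))
}
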