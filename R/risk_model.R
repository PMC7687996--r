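#' Risk-model specification
#'
#' One of four classifier families, each producing a probability-like risk
#' score in \[0, 1\]: a random forest (`ranger`), K-nearest neighbours
#' (`class::knn` on standardized features), gradient boosted trees
#' (`xgboost`), and L2-regularized logistic regression (`glmnet`, ridge).
#' Hyperparameters default to 500 trees for the forest, k = 11 neighbours,
#' 100 boosting rounds of depth 3 at learning rate 0.1, and ridge penalty
#' lambda = 1; all are overridable through `hyperparameters`.
#'
#' @param family one of `"random_forest"`, `"knn"`, `"gradient_boosting"`,
#'   `"logistic_l2"`.
#' @param hyperparameters named list of family-specific overrides.
#' @param seed integer seed fixed into the fit for reproducibility.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "knn",
                                  "gradient_boosting", "logistic_l2"),
                       hyperparameters = list(), seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(num_trees = 500L, mtry = NULL),
    knn = list(k = 11L),
    gradient_boosting = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    logistic_l2 = list(lambda = 1.0))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

fit_risk_model <- function(x, y, spec) {
  y <- as_binary_labels(y)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    random_forest = {
      ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                     probability = TRUE,
                     num.trees = hp$num_trees, mtry = hp$mtry,
                     seed = spec$seed, num.threads = 1)
    },
    knn = {
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      list(train = scale(x, ctr, scl), y = factor(y, levels = c(0, 1)),
           center = ctr, scale = scl, k = hp$k)
    },
    gradient_boosting = {
      xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                       objective = "binary:logistic",
                       nrounds = hp$nrounds, max_depth = hp$max_depth,
                       learning_rate = hp$eta, nthreads = 1,
                       seed = spec$seed, verbosity = 0)
    },
    logistic_l2 = {
      glmnet::glmnet(x, factor(y, levels = c(0, 1)), family = "binomial",
                     alpha = 0, lambda = hp$lambda)
    })
  structure(list(spec = spec, feature_names = colnames(x), fit = fit),
            class = "hypo_risk_model")
}

predict_risk <- function(model, x) {
  if (!identical(colnames(x), model$feature_names))
    stop("feature-name mismatch between scoring matrix and trained model")
  fit <- model$fit
  p <- switch(model$spec$family,
    random_forest = predict(fit, data = x, num.threads = 1)$predictions[, "1"],
    knn = {
      xs <- scale(x, fit$center, fit$scale)
      set.seed(model$spec$seed)          # knn breaks vote ties at random
      pr <- class::knn(fit$train, xs, fit$y, k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    gradient_boosting = predict(fit, x),
    logistic_l2 = as.numeric(predict(fit, x, type = "response")))
  pmin(pmax(as.numeric(p), 0), 1)
}

make_subject_folds <- function(subjects, positive_subjects, k, seed) {
  uniq <- sort(unique(subjects))
  strata <- split(uniq, uniq %in% positive_subjects)
  set.seed(seed)
  fold_of <- integer(0)
  ids <- character(0)
  for (s in strata) {
    s <- sample(s)
    fold_of <- c(fold_of, rep_len(seq_len(k), length(s)))
    ids <- c(ids, s)
  }
  setNames(fold_of, ids)
}

#' Subject-level tenfold cross-validation
#'
#' Folds partition SUBJECTS (never rows), stratified on whether a subject
#' contributes any positive row, so no subject's minutes appear on both
#' sides of a fold. Reports per-fold AUROC, AUPRC and Brier score, then
#' refits on all rows.
#'
#' @param x numeric feature matrix (one row per labeled minute).
#' @param y binary labels.
#' @param subjects subject id per row.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param keep_fold_models keep the per-fold fitted models (for
#'   out-of-fold scoring of the training stays; default `FALSE`).
#' @return List of class `hypo_cv` with `spec`, `fold_metrics` (data
#'   frame), `mean_auroc`, `mean_auprc`, `mean_brier`, `model` (refit on
#'   all rows), `fold_of` (named fold assignment) and optionally
#'   `fold_models`.
#' @export
cross_validate <- function(x, y, subjects, spec, k = 10L,
                           keep_fold_models = FALSE) {
  y <- as_binary_labels(y)
  pos_subj <- unique(subjects[y == 1])
  neg_subj <- setdiff(unique(subjects), pos_subj)
  if (length(pos_subj) < k || length(neg_subj) < k)
    stop("need at least k positive and k negative subjects for ", k, " folds")
  fold_of <- make_subject_folds(subjects, pos_subj, k, spec$seed)
  row_fold <- fold_of[subjects]
  metrics <- vector("list", k)
  fold_models <- if (keep_fold_models) vector("list", k) else NULL
  for (f in seq_len(k)) {
    tr <- row_fold != f
    te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
      stop("fold ", f, " lacks a class; use fewer folds or more subjects")
    m <- fit_risk_model(x[tr, , drop = FALSE], y[tr], spec)
    p <- predict_risk(m, x[te, , drop = FALSE])
    metrics[[f]] <- data.frame(fold = f,
                               auroc = auroc(p, y[te]),
                               auprc = auprc(p, y[te]),
                               brier = mean((p - y[te])^2),
                               n_test = sum(te))
    if (keep_fold_models) fold_models[[f]] <- m
  }
  fm <- do.call(rbind, metrics)
  structure(list(spec = spec, fold_metrics = fm,
                 mean_auroc = mean(fm$auroc),
                 mean_auprc = mean(fm$auprc),
                 mean_brier = mean(fm$brier),
                 model = fit_risk_model(x, y, spec),
                 fold_of = fold_of,
                 fold_models = fold_models),
            class = "hypo_cv")
}

#' Select a model family by calibration among equivalent discriminators
#'
#' Among the families whose mean cross-validated AUROC lies within
#' `auroc_tol` of the best, picks the one with the lowest (best) Brier
#' score.
#'
#' @param cv_results list of [cross_validate()] results.
#' @param auroc_tol AUROC equivalence tolerance (default 0.02).
#' @return The chosen element of `cv_results`.
#' @export
select_model <- function(cv_results, auroc_tol = 0.02) {
  if (length(cv_results) == 0) stop("no cross-validation results")
  aurocs <- vapply(cv_results, function(r) r$mean_auroc, numeric(1))
  briers <- vapply(cv_results, function(r) r$mean_brier, numeric(1))
  eligible <- which(aurocs >= max(aurocs) - auroc_tol)
  cv_results[[eligible[which.min(briers[eligible])]]]
}

#' Score feature rows with a trained risk model
#'
#' One risk score in \[0, 1\] per feature row; minutes with no feature row
#' (insufficient window data) receive no score. The feature columns must
#' match the training configuration exactly.
#'
#' @param model a fitted model (`hypo_risk_model`, e.g. the `model` element
#'   of [cross_validate()]).
#' @param features data frame from [build_feature_matrix()] (possibly
#'   row-bound over stays).
#' @return Data frame `stay_id, minute, score`.
#' @export
score_minutes <- function(model, features) {
  if (nrow(features) == 0)
    return(data.frame(stay_id = character(0), minute = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  x <- as.matrix(features[, feature_columns(features), drop = FALSE])
  data.frame(stay_id = features$stay_id,
             minute = features$end_minute,
             score = predict_risk(model, x),
             stringsAsFactors = FALSE)
}
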