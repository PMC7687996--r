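test_that("stacked features summarize trailing score windows causally", {
  sc <- data.frame(stay_id = "A", minute = 0:9,
                   score = seq(0, 0.9, by = 0.1))
  st <- build_stacked_features(sc)
  last <- st[st$minute == 9, ]
  expect_equal(last$lb5_mean, mean(c(0.5, 0.6, 0.7, 0.8, 0.9)))
  expect_equal(last$lb5_min, 0.5)
  expect_equal(last$lb5_max, 0.9)
  expect_equal(last$lb10_mean, mean(sc$score))
  expect_equal(last$time_since_admission, 9)
  # constant scores: sd identically zero
  stc <- build_stacked_features(data.frame(stay_id = "A", minute = 0:39,
                                           score = 0.7))
  expect_lt(max(stc$lb5_sd, stc$lb30_sd), 1e-12)
  expect_equal(stc$lb5_mean, rep(0.7, 40))
  # single available score: sd 0 by convention
  first <- st[st$minute == 0, ]
  expect_equal(first$lb30_sd, 0)
  # causality: truncating future scores leaves earlier rows unchanged
  st2 <- build_stacked_features(sc[sc$minute <= 5, ])
  common <- intersect(st$minute, st2$minute)
  expect_equal(st[st$minute %in% common, -1], st2[st2$minute %in% common, -1],
               ignore_attr = TRUE)
})

test_that("exceedances use the inclusive threshold convention", {
  sc <- data.frame(minute = 1:4, score = c(0.4, 0.6, 0.5, 0.7))
  expect_identical(raw_exceedances(sc, 0.5), 2:4)
  expect_identical(raw_exceedances(sc, 0), 1:4)
  expect_identical(raw_exceedances(sc, 1.01), integer(0))
})

test_that("raising the threshold never adds candidates", {
  set.seed(12)
  sc <- data.frame(minute = 1:200, score = runif(200))
  prev <- raw_exceedances(sc, 0)
  for (th in seq(0.1, 1, by = 0.1)) {
    cur <- raw_exceedances(sc, th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the lockout is greedy, spaced, idempotent and transparent at zero", {
  expect_identical(apply_lockout(c(0L, 10L, 20L), 15L), c(0L, 20L))
  expect_identical(apply_lockout(c(3L, 5L, 9L), 0L), c(3L, 5L, 9L))
  expect_identical(apply_lockout(42L, 15L), 42L)
  set.seed(4)
  for (rep in 1:25) {
    cand <- sort(sample(0:500, 60))
    em <- apply_lockout(cand, 15L)
    if (length(em) > 1) expect_true(all(diff(em) > 15))
    expect_identical(apply_lockout(em, 15L), em)
    expect_lte(length(em), length(cand))
  }
})

test_that("operational metrics follow their definitions", {
  # one subject, 2 h of monitoring, one alert before its event
  alerts <- data.frame(stay_id = "A", minute = 50L)
  onsets <- data.frame(stay_id = "A", onset_min = 90L)
  monitored <- data.frame(stay_id = "A", minutes = 120L)
  m <- adjudicate_and_summarize(alerts, onsets, monitored)
  expect_equal(m$alerts_per_subject_hour, 0.5)
  expect_equal(m$alert_level_ppv, 1)
  expect_equal(m$subject_sensitivity, 1)
  expect_equal(m$subject_miss_rate, 0)
  # alerts only after onset leave the subject missed
  m2 <- adjudicate_and_summarize(data.frame(stay_id = "A", minute = 95L),
                                 onsets, monitored)
  expect_equal(m2$subject_sensitivity, 0)
  expect_equal(m2$alert_level_ppv, 0)
  # alerts in event-free stays are false positives
  m3 <- adjudicate_and_summarize(
    data.frame(stay_id = c("A", "B"), minute = c(50L, 50L)),
    data.frame(stay_id = c("A", "B"), onset_min = c(90L, NA)),
    data.frame(stay_id = c("A", "B"), minutes = c(120L, 120L)))
  expect_equal(m3$alert_level_ppv, 0.5)
  # a finite true-positive horizon reclassifies distant alerts
  m4 <- adjudicate_and_summarize(alerts, onsets, monitored,
                                 max_horizon_min = 30)
  expect_equal(m4$alert_level_ppv, 0)
  expect_error(adjudicate_and_summarize(alerts, onsets,
                                        data.frame(stay_id = "A", minutes = 0L)),
               "zero monitored")
})

test_that("emitted alert streams respect the policy per stay", {
  sc <- data.frame(stay_id = rep(c("A", "B"), each = 30),
                   minute = rep(0:29, 2),
                   score = c(rep(0.9, 30), rep(0.1, 30)))
  al <- emit_alerts(sc, alert_policy(0.5, 15L))
  expect_identical(unique(al$stay_id), "A")
  expect_identical(al$minute, c(0L, 16L))
  expect_true(all(diff(al$minute) > 15))
})

test_that("an uninformative first stage leaves the stacked model at chance", {
  set.seed(21)
  n_subj <- 12
  scores <- do.call(rbind, lapply(1:n_subj, function(i)
    data.frame(stay_id = sprintf("T%02d", i), minute = 0:99,
               score = 0.5)))
  stacked <- build_stacked_features(scores)
  labels <- do.call(rbind, lapply(1:n_subj, function(i)
    data.frame(stay_id = sprintf("T%02d", i), end_minute = 80:99,
               label = if (i %% 2) "positive" else "negative",
               subject_id = sprintf("T%02d", i))))
  cv <- train_stacked(stacked, labels, model_spec("random_forest", seed = 2),
                      k = 3)
  expect_gte(cv$mean_auroc, 0.3)
  expect_lte(cv$mean_auroc, 0.7)
})
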