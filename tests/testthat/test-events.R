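test_that("below-threshold requires both inclusive thresholds and real data", {
  s <- make_series(4,
                   sbp = c(90, 85, NA, 120),
                   map = c(60, 65, 50, 85))
  expect_identical(below_threshold(s), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("a clean normal-range hour contains no events", {
  expect_identical(nrow(detect_hypotension_events(make_series(60))), 0L)
})

test_that("a single 10-min below run yields exactly one event containing it", {
  b <- rep(FALSE, 60)
  b[21:30] <- TRUE   # minutes 20..29
  ev <- detect_hypotension_events(series_from_pattern(b))
  expect_identical(nrow(ev), 1L)
  expect_lte(ev$onset_min, 20)
  expect_gte(ev$end_min, 29)
  expect_identical(ev[, c("onset_min", "end_min")],
                   oracle_detect(b)[, c("onset_min", "end_min")])
})

test_that("2-min gaps merge into one event, 3-min gaps split into two", {
  for (gap in c(2L, 3L)) {
    b <- rep(FALSE, 80)
    b[11:20] <- TRUE
    b[(21 + gap):(30 + gap)] <- TRUE
    ev <- detect_hypotension_events(series_from_pattern(b))
    expect_identical(nrow(ev), if (gap == 2L) 1L else 2L)
    expect_identical(ev[, c("onset_min", "end_min")],
                     oracle_detect(b)[, c("onset_min", "end_min")])
  }
})

test_that("stays shorter than the window produce no events", {
  b <- rep(TRUE, 9)
  expect_identical(nrow(detect_hypotension_events(series_from_pattern(b))), 0L)
})

test_that("detector matches the brute-force window oracle on random patterns", {
  set.seed(2024)
  for (rep in 1:200) {
    b <- runif(120) < runif(1, 0.15, 0.55)
    ev <- detect_hypotension_events(series_from_pattern(b))
    orc <- oracle_detect(b)
    expect_identical(ev$onset_min, orc$onset_min)
    expect_identical(ev$end_min, orc$end_min)
  }
})

test_that("events within a stay stay disjoint beyond the merge gap and contain a qualifying window", {
  set.seed(7)
  defn <- event_definition()
  for (rep in 1:50) {
    b <- runif(200) < 0.4
    ev <- detect_hypotension_events(series_from_pattern(b), defn)
    if (nrow(ev) > 1)
      expect_true(all(ev$onset_min[-1] - ev$end_min[-nrow(ev)] - 1 >
                        defn$merge_gap_max))
    for (i in seq_len(nrow(ev))) {
      # event boundaries are below-threshold minutes lying inside some
      # qualifying 10-min window
      expect_true(b[ev$onset_min[i] + 1] && b[ev$end_min[i] + 1])
      qualifying <- vapply(seq_len(length(b) - 9L), function(s)
        sum(b[s:(s + 9L)]) >= defn$min_below &&
          s - 1L <= ev$onset_min[i] && ev$onset_min[i] <= s + 8L,
        logical(1))
      expect_true(any(qualifying))
    }
  }
})

test_that("raising the SBP threshold never shrinks the below set", {
  set.seed(11)
  s <- make_series(100, sbp = rnorm(100, 95, 10), map = rnorm(100, 60, 5))
  lo <- below_threshold(s, event_definition(sbp_max = 85))
  hi <- below_threshold(s, event_definition(sbp_max = 100))
  expect_true(all(hi[lo]))
})

test_that("subjects are classified with the 2-hour intervention exclusion", {
  subjects <- data.frame(subject_id = c("S1", "S2", "S3", "S4"),
                         stay_id = c("A", "B", "C", "D"),
                         admission_datetime = as.POSIXct("2026-01-01",
                                                         tz = "UTC") + 1:4)
  events <- data.frame(stay_id = c("A", "B"),
                       onset_min = c(300L, 300L), end_min = c(320L, 320L))
  iv <- data.frame(subject_id = c("S1", "S2", "S3"),
                   stay_id = c("A", "B", "C"),
                   minute = c(200L, 150L, 100L),
                   type = "vasopressor")
  out <- classify_subjects(subjects, events, iv)
  # gap 100 <= 120: excluded
  expect_identical(out$group[out$subject_id == "S1"], "excluded")
  expect_match(out$exclusion_reason[out$subject_id == "S1"], "vasopressor")
  # gap 150 > 120: retained
  expect_identical(out$group[out$subject_id == "S2"], "hypotension")
  expect_identical(out$first_onset_min[out$subject_id == "S2"], 300L)
  # interventions without events leave the subject non-hypotensive
  expect_identical(out$group[out$subject_id == "S3"], "non-hypotension")
  expect_identical(out$group[out$subject_id == "S4"], "non-hypotension")
  # boundary: exactly 120 min before is excluded, 121 is retained
  iv$minute <- c(180L, 179L, 100L)
  out2 <- classify_subjects(subjects, events, iv)
  expect_identical(out2$group[out2$subject_id == "S1"], "excluded")
  expect_identical(out2$group[out2$subject_id == "S2"], "hypotension")
  # unknown stay is an error
  iv$stay_id[1] <- "Z"
  expect_error(classify_subjects(subjects, events, iv), "unknown stay")
})

test_that("time-to-first-event statistics summarize the hypotension group", {
  a <- data.frame(subject_id = c("S1", "S2", "S3", "S4"),
                  group = c("hypotension", "hypotension", "hypotension",
                            "non-hypotension"),
                  first_onset_min = c(60L, 120L, 180L, NA))
  st <- time_to_first_event_stats(a)
  expect_equal(st$mean, 120)
  expect_equal(st$median, 120)
  expect_identical(st$n, 3L)
  skewed <- a
  skewed$first_onset_min <- c(10L, 20L, 1000L, NA)
  expect_equal(time_to_first_event_stats(skewed)$median, 20)
  one <- a[1, ]
  st1 <- time_to_first_event_stats(one)
  expect_equal(st1$mean, 60)
  expect_true(is.na(st1$sd))
  expect_error(time_to_first_event_stats(a[4, ]), "no hypotension")
})
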