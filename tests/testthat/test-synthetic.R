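test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(frac_hypotensive = 1.2), "frac_hypotensive")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(sim_config(record_len_min = 60, drift_onset_lead_min = 90),
               "record_len_min")
  expect_error(sim_config(baseline_means = c(hr = 80, rr = 16, spo2 = 97,
                                             sbp = 500, dbp = 70)),
               "baseline_means")
})

test_that("frac_hypotensive = 0 yields only event-free subjects", {
  co <- generate_cohort(sim_config(n_subjects = 6, frac_hypotensive = 0,
                                   record_len_min = 400, seed = 3))
  expect_true(all(co$truth$group == "non-hypotensive"))
  expect_true(all(is.na(co$truth$programmed_onset_min)))
})

test_that("programmed onsets are present iff the subject is hypotensive", {
  co <- generate_cohort(sim_config(n_subjects = 12, record_len_min = 400,
                                   seed = 4), inject = FALSE)
  hyp <- co$truth$group == "hypotensive"
  expect_true(all(!is.na(co$truth$programmed_onset_min[hyp])))
  expect_true(all(is.na(co$truth$programmed_onset_min[!hyp])))
})

test_that("the same seed reproduces a bit-identical cohort", {
  cfg <- sim_config(n_subjects = 5, record_len_min = 400, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("clean hypotensive series realize their programmed event; clean
           event-free series produce no events", {
  co <- generate_cohort(sim_config(n_subjects = 50, record_len_min = 500,
                                   drift_depth_mmHg = 40, seed = 21),
                        inject = FALSE)
  errs <- c()
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    ev <- detect_hypotension_events(co$series[[tr$stay_id]])
    if (tr$group == "hypotensive") {
      expect_gte(nrow(ev), 1)
      errs <- c(errs, abs(ev$onset_min[1] - tr$programmed_onset_min))
    } else {
      expect_identical(nrow(ev), 0L)
    }
  }
  expect_lte(median(errs), 2)
  # the detected onset is also verified by the independent window oracle
  tr <- co$truth[which(co$truth$group == "hypotensive")[1], ]
  s <- co$series[[tr$stay_id]]
  orc <- oracle_detect(below_threshold(s))
  expect_lte(abs(orc$onset_min[1] - tr$programmed_onset_min), 2)
})

test_that("missingness injection hits its target rate in bursts", {
  s <- make_series(2000)
  expect_identical(inject_missingness(s, 0, seed = 1), s)
  s2 <- inject_missingness(s, 0.1, burst_max = 5, seed = 2)
  frac <- mean(is.na(s2$sbp))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
  # whole minutes are masked across channels
  expect_identical(is.na(s2$sbp), is.na(s2$hr))
  # burst lengths never exceed the maximum
  r <- rle(is.na(s2$sbp))
  expect_lte(max(r$lengths[r$values]), 5)
  expect_error(inject_missingness(s, 1), "rate")
})

test_that("artifact injection is invertible by plausibility cleaning", {
  s <- inject_missingness(make_series(1000), 0.05, seed = 3)
  expect_identical(inject_artifacts(s, 0, seed = 1)$series, s)
  ia <- inject_artifacts(s, 0.02, seed = 4)
  expect_gt(nrow(ia$injected), 0)
  bounds <- plausibility_bounds()
  for (j in seq_len(nrow(ia$injected))) {
    b <- bounds[[ia$injected$channel[j]]]
    expect_true(ia$injected$value[j] < b[1] || ia$injected$value[j] > b[2])
  }
  cl <- remove_artifacts(ia$series)
  # every injected value became missing ...
  for (j in seq_len(nrow(ia$injected))) {
    expect_true(is.na(cl$series[[ia$injected$channel[j]]][ia$injected$minute[j] + 1L]))
  }
  # ... and the missingness pattern is exactly pre-injection + injected
  for (ch in vital_channels()) {
    pre <- which(is.na(s[[ch]]))
    inj <- ia$injected$minute[ia$injected$channel == ch] + 1L
    expect_identical(which(is.na(cl$series[[ch]])), sort(union(pre, inj)))
  }
})

test_that("cohort CSV round-trips through the reader", {
  co <- generate_cohort(sim_config(n_subjects = 4, record_len_min = 400,
                                   missing_rate = 0.1, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_vitals(file.path(dir, "vitals.csv"),
                      subjects = read.csv(file.path(dir, "subjects.csv")))
  expect_identical(sort(names(back)), sort(co$truth$stay_id))
  for (st in co$truth$stay_id) {
    expect_equal(as.data.frame(back[[st]]), as.data.frame(co$series[[st]]),
                 tolerance = 1e-12)
    expect_equal(as.numeric(attr(back[[st]], "admission")),
                 as.numeric(co$truth$admission_datetime[co$truth$stay_id == st]),
                 tolerance = 1)
  }
})
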