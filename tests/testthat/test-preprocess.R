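test_that("plausibility bounds are strict: boundary values survive, beyond-boundary values are removed", {
  s <- make_series(6,
                   sbp = c(5, 10, 400, 401, 120, NA),
                   hr = c(9, 10, 400, 401, 80, 80),
                   spo2 = c(9, 10, 97, 97, 97, 97),
                   rr = c(0.5, 1, 100, 101, 16, 16))
  out <- remove_artifacts(s)
  expect_identical(which(is.na(out$series$sbp)), c(1L, 4L, 6L))
  expect_identical(which(is.na(out$series$hr)), c(1L, 4L))
  expect_identical(which(is.na(out$series$spo2)), 1L)
  expect_identical(which(is.na(out$series$rr)), c(1L, 4L))
  expect_identical(unname(out$removed[c("sbp", "hr", "spo2", "rr")]),
                   c(2L, 2L, 1L, 2L))
  # untouched channels keep their values exactly
  expect_identical(out$series$dbp, s$dbp)
})

test_that("cleaning is idempotent", {
  s <- inject_artifacts(make_series(500), 0.05, seed = 2)$series
  once <- remove_artifacts(s)
  twice <- remove_artifacts(once$series)
  expect_identical(once$series, twice$series)
  expect_true(all(twice$removed == 0L))
})

test_that("imputation fills short gaps with the mean of the three previous values", {
  x <- c(100, 102, 104, NA, 110)
  s <- make_series(5, sbp = x)
  out <- impute_missing(s)
  expect_equal(out$sbp[4], mean(c(100, 102, 104)))
  expect_equal(out$sbp[5], 110)  # observed values never altered
  # cascading: filled values serve as previous values within a run
  x2 <- c(100, 102, 104, NA, NA)
  out2 <- impute_missing(make_series(5, sbp = x2))
  f1 <- mean(c(100, 102, 104))
  expect_equal(out2$sbp[4], f1)
  expect_equal(out2$sbp[5], mean(c(102, 104, f1)))
  # fewer than three prior values: mean of those available
  out3 <- impute_missing(make_series(3, sbp = c(100, NA, NA)))
  expect_equal(out3$sbp[2], 100)
  expect_equal(out3$sbp[3], 100)
})

test_that("runs of ten or more missing minutes are never imputed", {
  x <- c(rep(100, 5), rep(NA, 10), rep(100, 5))
  out <- impute_missing(make_series(20, sbp = x))
  expect_identical(which(is.na(out$sbp)), 6:15)
  x9 <- c(rep(100, 5), rep(NA, 9), rep(100, 5))
  out9 <- impute_missing(make_series(19, sbp = x9))
  expect_false(anyNA(out9$sbp))
})

test_that("leading missing minutes stay missing and imputation is causal", {
  out <- impute_missing(make_series(5, sbp = c(NA, NA, 100, NA, 102)))
  expect_true(all(is.na(out$sbp[1:2])))
  expect_equal(out$sbp[4], 100)
  # causality: truncating the future does not change earlier fills
  set.seed(42)
  x <- rnorm(300, 120, 5)
  x[sample(300, 60)] <- NA
  full <- impute_missing(make_series(300, sbp = x))
  for (cut in c(50, 120, 250)) {
    part <- impute_missing(make_series(cut, sbp = x[1:cut]))
    expect_equal(part$sbp, full$sbp[1:cut])
  }
})

test_that("cleaning and imputation preserve the grid exactly", {
  s <- inject_missingness(make_series(400), 0.2, seed = 9)
  out <- preprocess_series(inject_artifacts(s, 0.02, seed = 1)$series)
  expect_identical(nrow(out$series), 400L)
  expect_identical(out$series$minute, 0:399)
})

test_that("the vitals reader regularizes gaps and rejects duplicates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "v.csv")
  hdr <- "subject_id,stay_id,minute,hr,rr,spo2,sbp,dbp,map"
  writeLines(c(hdr,
               "S1,A,0,80,16,97,120,70,86",
               "S1,A,1,81,16,97,121,70,87",
               "S1,A,3,82,16,97,122,70,87"), path)
  out <- read_vitals(path)
  expect_length(out, 1)
  expect_identical(nrow(out[["A"]]), 4L)
  expect_true(is.na(out[["A"]]$sbp[3]))
  writeLines(hdr, path)
  expect_identical(read_vitals(path), list())
  writeLines(c(hdr,
               "S1,A,0,80,16,97,120,70,86",
               "S1,A,0,80,16,97,120,70,86"), path)
  expect_error(read_vitals(path), "duplicate")
  writeLines(c(paste0(hdr, ",extra"),
               "S1,A,0,80,16,97,120,70,86,1"), path)
  expect_error(read_vitals(path), "unknown columns")
})

test_that("imputation error is zero on constants and 2s on a unit ramp", {
  s <- make_series(60, sbp = rep(100, 60))
  q <- imputation_quality(s, mask_len = 3, n_masks = 5, seed = 1)
  expect_equal(q$rmse[q$channel == "sbp"], 0)
  # linear ramp with slope s: the mean of the three points before a single
  # masked minute trails the truth by exactly 2s
  slope <- 1.5
  ramp <- 100 + slope * (0:59)
  q2 <- imputation_quality(make_series(60, sbp = ramp), mask_len = 1,
                           n_masks = 10, seed = 2)
  expect_equal(q2$rmse[q2$channel == "sbp"], 2 * slope, tolerance = 1e-10)
  expect_equal(q2$bias[q2$channel == "sbp"], -2 * slope, tolerance = 1e-10)
  # a series with no complete segment long enough is an error
  allna <- make_series(20, sbp = rep(NA_real_, 20), hr = rep(NA_real_, 20),
                       rr = rep(NA_real_, 20), spo2 = rep(NA_real_, 20),
                       dbp = rep(NA_real_, 20), map = rep(NA_real_, 20))
  expect_error(imputation_quality(allna, mask_len = 3), "maskable")
})
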