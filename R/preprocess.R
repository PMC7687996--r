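#' Physiological plausibility bounds
#'
#' Open exclusion bounds per channel: a value strictly below the low bound or
#' strictly above the high bound is physiologically implausible and removed;
#' values exactly on a bound are kept. Pressures (SBP, DBP, MAP) are bounded
#' by (10, 400) mmHg, respiratory rate by (1, 100) breaths/min, heart rate by
#' (10, 400) beats/min, and SpO2 has a low bound of 10% with no upper
#' exclusion bound.
#'
#' @return Named list of `c(low, high)` pairs, one per channel.
#' @export
plausibility_bounds <- function() {
  list(hr   = c(10, 400),
       rr   = c(1, 100),
       spo2 = c(10, Inf),
       sbp  = c(10, 400),
       dbp  = c(10, 400),
       map  = c(10, 400))
}

#' Imputation configuration
#'
#' @param lookback_points number of most recent available values averaged to
#'   fill a missing minute (default 3).
#' @param max_gap_min gaps of this many minutes or longer are never imputed
#'   (default 10: runs of up to 9 consecutive missing minutes are fillable).
#' @return List of class `imputation_config`.
#' @export
imputation_config <- function(lookback_points = 3L, max_gap_min = 10L) {
  if (lookback_points < 1) stop("lookback_points must be >= 1")
  if (max_gap_min < 1) stop("max_gap_min must be >= 1")
  structure(list(lookback_points = as.integer(lookback_points),
                 max_gap_min = as.integer(max_gap_min)),
            class = "imputation_config")
}

#' Read vital-sign series from a cohort CSV
#'
#' Reads the cohort vitals dialect (columns `subject_id, stay_id, minute,
#' hr, rr, spo2, sbp, dbp, map`; empty cell = missing) and returns one
#' [vital_series()] per stay, each regularized onto a contiguous 0-based
#' minute grid. Duplicated `(stay_id, minute)` rows are an error.
#'
#' @param path path to the vitals CSV.
#' @param subjects optional subjects table (as written by [write_cohort()])
#'   supplying admission datetimes.
#' @return List of `vital_series`, named by stay id.
#' @export
read_vitals <- function(path, subjects = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "stay_id", "minute", vital_channels())
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("vitals file lacks columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra) > 0)
    stop("vitals file has unknown columns: ", paste(extra, collapse = ", "))
  if (nrow(df) == 0) return(list())
  if (anyNA(df$minute))
    stop("malformed vitals row: missing minute at line ",
         which(is.na(df$minute))[1] + 1L)
  dup <- duplicated(df[, c("stay_id", "minute")])
  if (any(dup))
    stop("duplicate (stay_id, minute) row at line ", which(dup)[1] + 1L)
  out <- lapply(split(df, df$stay_id), function(d) {
    d <- d[order(d$minute), ]
    adm <- as.POSIXct("2026-01-01", tz = "UTC")
    if (!is.null(subjects)) {
      hit <- match(d$stay_id[1], subjects$stay_id)
      if (!is.na(hit))
        adm <- as.POSIXct(subjects$admission_datetime[hit], tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                         "%Y-%m-%d %H:%M:%OS",
                                         "%Y-%m-%d"))
    }
    vital_series(d$minute, d$hr, d$rr, d$spo2, d$sbp, d$dbp, d$map,
                 subject_id = d$subject_id[1], stay_id = d$stay_id[1],
                 admission = adm)
  })
  out[order(names(out))]
}

#' Remove physiologically implausible values
#'
#' Any channel value strictly outside its [plausibility_bounds()] becomes
#' missing; every other value is untouched. The operation is idempotent.
#'
#' @param series a [vital_series()].
#' @param bounds bounds list, by default [plausibility_bounds()].
#' @return List with elements `series` (cleaned) and `removed` (named integer
#'   vector of per-channel removal counts).
#' @export
remove_artifacts <- function(series, bounds = plausibility_bounds()) {
  removed <- setNames(integer(length(vital_channels())), vital_channels())
  data <- series
  for (ch in vital_channels()) {
    b <- bounds[[ch]]
    bad <- !is.na(data[[ch]]) & (data[[ch]] < b[1] | data[[ch]] > b[2])
    removed[ch] <- sum(bad)
    data[[ch]][bad] <- NA_real_
  }
  list(series = with_channels(series, data), removed = removed)
}

# fill one channel vector causally; see impute_missing for the contract
impute_channel <- function(x, lookback, max_gap) {
  isna <- is.na(x)
  if (!any(isna)) return(x)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    if (r$lengths[i] >= max_gap) next           # gap too long: never imputed
    for (pos in starts[i]:ends[i]) {
      prior <- which(!is.na(x[seq_len(pos - 1L)]))
      if (length(prior) == 0) break             # leading gap: no past data
      use <- tail(prior, lookback)
      x[pos] <- mean(x[use])
    }
  }
  x
}

#' Impute short gaps with a causal moving average
#'
#' A run of missing minutes shorter than `max_gap_min` is filled
#' left-to-right; each filled minute becomes the mean of the
#' `lookback_points` most recent available values, where values filled
#' earlier in the same run count as available (signal-stability reading).
#' Runs of `max_gap_min` minutes or longer are left missing, as are leading
#' gaps with no past data. No future value is ever used, so the imputation
#' is causal: truncating the series after minute t cannot change any filled
#' value at or before t.
#'
#' @param series a [vital_series()] on a regular grid.
#' @param config an [imputation_config()].
#' @return The series with short gaps filled.
#' @export
impute_missing <- function(series, config = imputation_config()) {
  data <- series
  for (ch in vital_channels())
    data[[ch]] <- impute_channel(series[[ch]], config$lookback_points,
                                 config$max_gap_min)
  with_channels(series, data)
}

#' Assess imputation error on known-complete segments
#'
#' Masks randomly placed sub-segments of complete data, imputes them, and
#' compares against the held-out truth, reporting per-channel RMSE and bias.
#' Masks of `max_gap_min` minutes or longer would not be imputed and are not
#' requested.
#'
#' @param series a cleaned [vital_series()].
#' @param mask_len length in minutes of each mask (must be < `max_gap_min`).
#' @param n_masks number of masks attempted per channel.
#' @param config an [imputation_config()].
#' @param seed integer seed for mask placement.
#' @return Data frame with one row per channel: `channel, n_masked, rmse,
#'   bias`.
#' @export
imputation_quality <- function(series, mask_len = 3L, n_masks = 20L,
                               config = imputation_config(), seed = 1L) {
  if (mask_len >= config$max_gap_min)
    stop("mask_len must be shorter than max_gap_min (longer gaps are not imputed)")
  need <- config$lookback_points + mask_len
  set.seed(seed)
  rows <- lapply(vital_channels(), function(ch) {
    x <- series[[ch]]
    ok <- !is.na(x)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- which(r$values & r$lengths >= need)
    if (length(segs) == 0) return(NULL)
    err <- numeric(0)
    for (k in seq_len(n_masks)) {
      seg <- segs[sample.int(length(segs), 1)]
      lo <- starts[seg] + config$lookback_points
      hi <- ends[seg] - mask_len + 1L
      if (hi < lo) next
      at <- sample(lo:hi, 1)
      masked <- x
      idx <- at:(at + mask_len - 1L)
      masked[idx] <- NA_real_
      filled <- impute_channel(masked, config$lookback_points,
                               config$max_gap_min)
      err <- c(err, filled[idx] - x[idx])
    }
    if (length(err) == 0) return(NULL)
    data.frame(channel = ch, n_masked = length(err),
               rmse = sqrt(mean(err^2)), bias = mean(err))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no maskable complete segment in any channel")
  do.call(rbind, rows)
}

#' Clean and impute one series
#'
#' Convenience wrapper: [remove_artifacts()] followed by [impute_missing()].
#' @inheritParams remove_artifacts
#' @inheritParams impute_missing
#' @return List with `series` (cleaned, imputed) and `removed` counts.
#' @export
preprocess_series <- function(series, bounds = plausibility_bounds(),
                              config = imputation_config()) {
  cl <- remove_artifacts(series, bounds)
  list(series = impute_missing(cl$series, config), removed = cl$removed)
}
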