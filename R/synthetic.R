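#' Synthetic ICU cohort configuration
#'
#' Parameters of the synthetic minute-by-minute vital-sign simulator. Each
#' subject contributes one ICU stay on a 1-minute grid with subject-specific
#' baselines and first-order autoregressive (AR(1)) noise per channel.
#' Hypotensive subjects receive a programmed decompensation: SBP and DBP
#' glide down from `drift_onset_lead_min` minutes before the programmed
#' onset to just above the hypotension thresholds, drop at the onset to a
#' depressed plateau `drift_depth_mmHg` below baseline (DBP declines by 70%
#' of that depth so the derived MAP also crosses its threshold), hold for
#' `plateau_min`, then recover; heart rate ramps up 10 beats/min in
#' parallel. MAP is derived as (SBP + 2 DBP)/3 plus unit-variance noise.
#'
#' @param n_subjects number of subjects (one stay each).
#' @param frac_hypotensive fraction in \[0,1\] of subjects given a programmed
#'   hypotension event.
#' @param record_len_min record length in minutes (default 1440 = 24 h).
#' @param baseline_means,baseline_sd named per-channel setpoints and
#'   between/within-subject noise SDs for `hr, rr, spo2, sbp, dbp`.
#' @param ar_coefficient AR(1) coefficient of the minute-scale noise, in
#'   \[0,1).
#' @param drift_onset_lead_min minutes before the programmed onset at which
#'   the blood-pressure decline begins.
#' @param drift_depth_mmHg SBP depth of the post-onset plateau below the
#'   subject's baseline.
#' @param plateau_min,recovery_min duration of the depressed plateau and of
#'   the linear recovery back to baseline.
#' @param missing_rate,missing_burst_max_min target fraction of minutes
#'   masked as missing, grouped in bursts of at most `missing_burst_max_min`
#'   minutes.
#' @param artifact_rate fraction of minutes receiving an out-of-range
#'   artifact value.
#' @param admission_date_spread_days admission datetimes are drawn uniformly
#'   over this many days so a chronological split is well defined.
#' @param seed integer seed; the same config yields a bit-identical cohort.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200L,
                       frac_hypotensive = 0.5,
                       record_len_min = 1440L,
                       baseline_means = c(hr = 80, rr = 16, spo2 = 97,
                                          sbp = 120, dbp = 70),
                       baseline_sd = c(hr = 3, rr = 2, spo2 = 1,
                                       sbp = 5, dbp = 4),
                       ar_coefficient = 0.9,
                       drift_onset_lead_min = 90L,
                       drift_depth_mmHg = 35,
                       plateau_min = 30L,
                       recovery_min = 60L,
                       missing_rate = 0.05,
                       missing_burst_max_min = 5L,
                       artifact_rate = 0.002,
                       admission_date_spread_days = 30,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              frac_hypotensive = frac_hypotensive,
              record_len_min = as.integer(record_len_min),
              baseline_means = baseline_means,
              baseline_sd = baseline_sd,
              ar_coefficient = ar_coefficient,
              drift_onset_lead_min = as.integer(drift_onset_lead_min),
              drift_depth_mmHg = drift_depth_mmHg,
              plateau_min = as.integer(plateau_min),
              recovery_min = as.integer(recovery_min),
              missing_rate = missing_rate,
              missing_burst_max_min = as.integer(missing_burst_max_min),
              artifact_rate = artifact_rate,
              admission_date_spread_days = admission_date_spread_days,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop(sprintf("invalid sim_config: field '%s' %s", field, why), call. = FALSE)
  if (cfg$n_subjects < 1) bad("n_subjects", "must be >= 1")
  for (f in c("frac_hypotensive", "missing_rate", "artifact_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) bad(f, "must lie in [0, 1]")
  }
  if (cfg$missing_rate >= 1) bad("missing_rate", "must be < 1")
  if (cfg$artifact_rate >= 1) bad("artifact_rate", "must be < 1")
  if (cfg$ar_coefficient < 0 || cfg$ar_coefficient >= 1)
    bad("ar_coefficient", "must lie in [0, 1)")
  if (cfg$record_len_min <= cfg$drift_onset_lead_min)
    bad("record_len_min", "must exceed drift_onset_lead_min")
  nm <- c("hr", "rr", "spo2", "sbp", "dbp")
  if (!all(nm %in% names(cfg$baseline_means)))
    bad("baseline_means", "must name hr, rr, spo2, sbp, dbp")
  if (!all(nm %in% names(cfg$baseline_sd)))
    bad("baseline_sd", "must name hr, rr, spo2, sbp, dbp")
  bounds <- plausibility_bounds()
  for (ch in nm) {
    b <- bounds[[ch]]
    v <- cfg$baseline_means[[ch]]
    if (v < b[1] || v > b[2])
      bad("baseline_means", sprintf("setpoint for %s outside plausibility bounds", ch))
  }
  if (cfg$drift_depth_mmHg <= 0) bad("drift_depth_mmHg", "must be positive")
  if (cfg$missing_burst_max_min < 1) bad("missing_burst_max_min", "must be >= 1")
  invisible(cfg)
}

# stationary AR(1) noise, marginal sd = sd
ar1_noise <- function(n, ar, sd) {
  if (n == 0) return(numeric(0))
  innov <- c(rnorm(1, 0, sd), rnorm(n - 1, 0, sd * sqrt(1 - ar^2)))
  as.numeric(stats::filter(innov, ar, method = "recursive"))
}

# piecewise-linear decompensation trend (additive, <= 0 for pressures).
# Glides from 0 at onset-lead to `anchor` at onset-1 (just above threshold),
# steps to -depth at onset, holds for plateau, recovers linearly.
drift_trend <- function(n, onset, lead, anchor, depth, plateau, recovery) {
  tr <- numeric(n)
  t <- seq_len(n) - 1L
  ramp <- t >= (onset - lead) & t < onset
  if (any(ramp))
    tr[ramp] <- anchor * (t[ramp] - (onset - lead)) / max(lead - 1L, 1L)
  plat <- t >= onset & t < onset + plateau
  tr[plat] <- -depth
  rec <- t >= onset + plateau & t < onset + plateau + recovery
  if (any(rec))
    tr[rec] <- -depth * (1 - (t[rec] - onset - plateau) / recovery)
  tr
}

#' Generate a synthetic ICU cohort
#'
#' Draws one stay per subject under `config`. Hypotensive subjects receive a
#' programmed decompensation whose post-onset minutes are guaranteed (before
#' missingness/artifact injection) to satisfy the hypotension event
#' definition — SBP <= 90 and MAP <= 60 for at least 10 consecutive minutes
#' from the programmed onset — while every clean minute outside the
#' decompensation episode, and every minute of a non-hypotensive subject, is
#' guaranteed to stay above at least one threshold. The generator enforces
#' these guarantees by construction (a mild clamp on the small fraction of
#' noise excursions that would violate them).
#'
#' Output is deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param inject if `TRUE` (default) the configured missingness bursts and
#'   out-of-range artifacts are injected into the returned series; if
#'   `FALSE` the clean series are returned (useful for event-detection
#'   ground truth).
#' @return List with elements `series` (list of [vital_series()]) and
#'   `truth` (data frame: `subject_id, stay_id, group, programmed_onset_min,
#'   admission_datetime`), plus `interventions`, an empty intervention table
#'   to be filled by the caller when exclusion scenarios are wanted.
#' @export
generate_cohort <- function(config, inject = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  len <- config$record_len_min
  n_hyp <- round(n * config$frac_hypotensive)
  group <- rep("non-hypotensive", n)
  if (n_hyp > 0) group[sample.int(n, n_hyp)] <- "hypotensive"
  origin <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  # whole seconds: admissions survive the CSV round trip exactly
  admission <- origin + round(runif(n, 0, config$admission_date_spread_days * 86400))

  onset_lo <- max(config$drift_onset_lead_min + 1L, 240L)
  onset_hi <- len - (config$plateau_min + 30L)
  if (onset_hi < onset_lo)
    stop("invalid sim_config: field 'record_len_min' too short to place a programmed onset")

  per_subject_seed <- sample.int(.Machine$integer.max, n)
  series <- vector("list", n)
  onset <- rep(NA_integer_, n)
  bm <- config$baseline_means
  bs <- config$baseline_sd
  for (i in seq_len(n)) {
    set.seed(per_subject_seed[i])
    hyp <- group[i] == "hypotensive"
    if (hyp) onset[i] <- as.integer(round(runif(1, onset_lo, onset_hi)))
    # subject-specific baseline offsets (between-subject variation)
    base <- c(hr = bm[["hr"]] + rnorm(1, 0, bs[["hr"]]),
              rr = bm[["rr"]] + rnorm(1, 0, bs[["rr"]] / 2),
              spo2 = min(bm[["spo2"]] + rnorm(1, 0, bs[["spo2"]] / 2), 100),
              sbp = bm[["sbp"]] + rnorm(1, 0, bs[["sbp"]]),
              dbp = bm[["dbp"]] + rnorm(1, 0, bs[["dbp"]]))
    hr <- base[["hr"]] + ar1_noise(len, config$ar_coefficient, bs[["hr"]])
    rr <- base[["rr"]] + ar1_noise(len, config$ar_coefficient, bs[["rr"]])
    spo2 <- pmin(base[["spo2"]] + ar1_noise(len, config$ar_coefficient, bs[["spo2"]]), 100)
    sbp <- base[["sbp"]] + ar1_noise(len, config$ar_coefficient, bs[["sbp"]])
    dbp <- base[["dbp"]] + ar1_noise(len, config$ar_coefficient, bs[["dbp"]])
    episode <- rep(FALSE, len)
    if (hyp) {
      o <- onset[i]
      lead <- config$drift_onset_lead_min
      # pre-onset glide targets just above the definitional thresholds so the
      # detected onset coincides with the programmed one
      sbp_anchor <- min(93 - base[["sbp"]], 0)
      dbp_anchor <- min(46 - base[["dbp"]], 0)
      sbp <- sbp + drift_trend(len, o, lead, sbp_anchor, config$drift_depth_mmHg,
                               config$plateau_min, config$recovery_min)
      dbp <- dbp + drift_trend(len, o, lead, dbp_anchor,
                               0.7 * config$drift_depth_mmHg,
                               config$plateau_min, config$recovery_min)
      hr <- hr - drift_trend(len, o, lead, -5, 10,
                             config$plateau_min, config$recovery_min)
      t <- seq_len(len) - 1L
      # only the programmed event (plateau + recovery) may be jointly below
      # threshold; the pre-onset glide stays above so the detected onset
      # coincides with the programmed one
      episode <- t >= o & t < (o + config$plateau_min + config$recovery_min)
      # guarantee a definitional event from the programmed onset
      evt <- t >= o & t < (o + max(15L, 10L))
      sbp[evt] <- pmin(sbp[evt], 88)
      dbp[evt] <- pmin(dbp[evt], 43)
    }
    map <- (sbp + 2 * dbp) / 3 + rnorm(len, 0, 1)
    if (hyp) {
      evt <- (seq_len(len) - 1L) >= onset[i] &
        (seq_len(len) - 1L) < (onset[i] + 15L)
      map[evt] <- pmin(map[evt], 59)
    }
    # guarantee above-threshold outside the decompensation episode
    bad <- !episode & sbp <= 90 & map <= 60
    if (any(bad)) {
      sbp[bad] <- pmax(sbp[bad], 92)
      map[bad] <- pmax(map[bad], 61)
    }
    s <- vital_series(0:(len - 1L), hr, rr, spo2, sbp, dbp, map,
                      subject_id = sprintf("S%04d", i),
                      stay_id = sprintf("ICU%04d", i),
                      admission = admission[i])
    if (inject) {
      if (config$missing_rate > 0)
        s <- inject_missingness(s, config$missing_rate,
                                config$missing_burst_max_min,
                                seed = per_subject_seed[i] %% 1000003L)
      if (config$artifact_rate > 0)
        s <- inject_artifacts(s, config$artifact_rate,
                              seed = per_subject_seed[i] %% 999983L)$series
    }
    series[[i]] <- s
  }
  truth <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                      stay_id = sprintf("ICU%04d", seq_len(n)),
                      group = group,
                      programmed_onset_min = onset,
                      admission_datetime = admission,
                      stringsAsFactors = FALSE)
  interventions <- data.frame(subject_id = character(0),
                              stay_id = character(0),
                              minute = integer(0), type = character(0),
                              stringsAsFactors = FALSE)
  names(series) <- truth$stay_id
  list(series = series, truth = truth, interventions = interventions)
}

#' Mask minutes as missing, in bursts
#'
#' Masks whole minutes (all channels) until the target fraction is reached,
#' drawing burst start positions uniformly and burst lengths uniformly in
#' `1..burst_max`. For records of 1000+ minutes the realized missing
#' fraction lands within a few percent (relative) of `rate`.
#'
#' @param series a [vital_series()].
#' @param rate target missing fraction, in \[0, 1).
#' @param burst_max maximum burst length in minutes.
#' @param seed integer seed.
#' @return The series with masked minutes set to `NA` on every channel.
#' @export
inject_missingness <- function(series, rate, burst_max = 5L, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("missing rate must lie in [0, 1)")
  if (rate == 0) return(series)
  n <- nrow(series)
  target <- round(rate * n)
  if (target == 0) return(series)
  set.seed(seed)
  masked <- rep(FALSE, n)
  guard <- 0L
  while (sum(masked) < target && guard < 200L * target) {
    guard <- guard + 1L
    start <- sample.int(n, 1)
    want <- sample.int(burst_max, 1)
    idx <- start:min(start + want - 1L, n)
    # keep bursts separated so no realized gap exceeds burst_max
    hood <- max(1L, start - 1L):min(start + want, n)
    if (any(masked[hood])) next
    remaining <- target - sum(masked)
    if (length(idx) > remaining) idx <- idx[seq_len(remaining)]
    masked[idx] <- TRUE
  }
  data <- series
  for (ch in vital_channels()) data[[ch]][masked] <- NA_real_
  with_channels(series, data)
}

#' Inject out-of-range artifact values
#'
#' Replaces values at a known set of minutes with values that violate the
#' [plausibility_bounds()] for the chosen channel (e.g. SBP drawn from
#' (400, 500]), so that [remove_artifacts()] is guaranteed to flag exactly
#' those positions.
#'
#' @param series a [vital_series()].
#' @param rate fraction of minutes to corrupt, in \[0, 1).
#' @param seed integer seed.
#' @return List with `series` (corrupted) and `injected`, a data frame of
#'   `minute, channel, value` for every injected artifact.
#' @export
inject_artifacts <- function(series, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("artifact rate must lie in [0, 1)")
  empty <- data.frame(minute = integer(0), channel = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  if (rate == 0) return(list(series = series, injected = empty))
  n <- nrow(series)
  k <- round(rate * n)
  if (k == 0) return(list(series = series, injected = empty))
  set.seed(seed)
  minutes <- sample.int(n, k) - 1L      # 0-based minute indices
  chans <- sample(vital_channels(), k, replace = TRUE)
  value <- numeric(k)
  for (j in seq_len(k)) {
    value[j] <- switch(chans[j],
      sbp = , dbp = , map = if (runif(1) < 0.5) runif(1, 400 + 1e-6, 500) else runif(1, 0, 10 - 1e-6),
      hr = if (runif(1) < 0.5) runif(1, 400 + 1e-6, 500) else runif(1, 0, 10 - 1e-6),
      rr = if (runif(1) < 0.5) runif(1, 100 + 1e-6, 150) else runif(1, 0, 1 - 1e-6),
      spo2 = runif(1, 0, 10 - 1e-6))
  }
  data <- series
  for (j in seq_len(k)) data[[chans[j]]][minutes[j] + 1L] <- value[j]
  inj <- data.frame(minute = minutes, channel = chans, value = value,
                    stringsAsFactors = FALSE)
  inj <- inj[order(inj$minute), ]
  rownames(inj) <- NULL
  list(series = with_channels(series, data), injected = inj)
}

#' Write a cohort to CSV files
#'
#' Writes `vitals.csv` (`subject_id, stay_id, minute, hr, rr, spo2, sbp,
#' dbp, map`; missing = empty cell), `subjects.csv` (`subject_id, stay_id,
#' admission_datetime` ISO-8601, `group, programmed_onset_min`) and
#' `interventions.csv` (`subject_id, stay_id, minute, type`).
#'
#' @param cohort a list as returned by [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vit <- do.call(rbind, lapply(cohort$series, function(s) {
    cbind(data.frame(subject_id = subject_id_of(s), stay_id = stay_id_of(s)),
          as.data.frame(s)[, c("minute", vital_channels())])
  }))
  rownames(vit) <- NULL
  subj <- cohort$truth
  subj$admission_datetime <- format(subj$admission_datetime,
                                    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- c(vitals = file.path(dir, "vitals.csv"),
             subjects = file.path(dir, "subjects.csv"),
             interventions = file.path(dir, "interventions.csv"))
  write.csv(vit, paths["vitals"], row.names = FALSE, na = "")
  write.csv(subj, paths["subjects"], row.names = FALSE, na = "")
  write.csv(cohort$interventions, paths["interventions"], row.names = FALSE, na = "")
  invisible(paths)
}
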