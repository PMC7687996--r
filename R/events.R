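#' Hypotension event definition
#'
#' A minute is below threshold when SBP <= `sbp_max` AND MAP <= `map_max`
#' (both inclusive). A 10-minute sliding window qualifies when at least
#' `min_below` of its minutes are below threshold; the union of qualifying
#' windows' minutes forms candidate periods, and periods separated by at
#' most `merge_gap_max` minutes are combined into a single event.
#'
#' @param sbp_max systolic threshold, mmHg (default 90).
#' @param map_max mean arterial pressure threshold, mmHg (default 60).
#' @param window_len sliding window length in minutes (default 10).
#' @param min_below minimum below-threshold minutes per qualifying window
#'   (default 5).
#' @param merge_gap_max maximum gap in minutes merged between candidate
#'   periods (default 2).
#' @return List of class `event_definition`.
#' @export
event_definition <- function(sbp_max = 90, map_max = 60, window_len = 10L,
                             min_below = 5L, merge_gap_max = 2L) {
  if (min_below > window_len) stop("min_below must not exceed window_len")
  if (any(c(sbp_max, map_max, window_len, min_below) <= 0) || merge_gap_max < 0)
    stop("event definition parameters must be positive")
  structure(list(sbp_max = sbp_max, map_max = map_max,
                 window_len = as.integer(window_len),
                 min_below = as.integer(min_below),
                 merge_gap_max = as.integer(merge_gap_max)),
            class = "event_definition")
}

#' Per-minute below-threshold indicator
#'
#' `TRUE` at a minute iff both SBP <= `sbp_max` and MAP <= `map_max`. A
#' minute with missing SBP or MAP is never below threshold (hypotension is
#' not inferred from absent data).
#'
#' @param series a [vital_series()] (or any data frame with `sbp`, `map`).
#' @param defn an [event_definition()].
#' @return Logical vector, one element per minute.
#' @export
below_threshold <- function(series, defn = event_definition()) {
  b <- series$sbp <= defn$sbp_max & series$map <= defn$map_max
  b[is.na(b)] <- FALSE
  b
}

# maximal runs of TRUE -> data.frame(start, end) of 0-based minute indices
runs_of <- function(flag) {
  if (!any(flag)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Detect hypotension events in one stay
#'
#' Slides a `window_len`-minute window every minute; windows with at least
#' `min_below` below-threshold minutes qualify. The below-threshold minutes
#' covered by qualifying windows form the candidate sub-threshold periods;
#' periods separated by at most `merge_gap_max` minutes are combined into a
#' single event. Each merged period becomes one event whose onset is its
#' first minute and whose end is its last minute (both below threshold by
#' construction). Series shorter than the window yield no events.
#'
#' @param series a cleaned, imputed [vital_series()].
#' @param defn an [event_definition()].
#' @return Data frame `stay_id, onset_min, end_min`, sorted by onset;
#'   zero rows when no event is present.
#' @export
detect_hypotension_events <- function(series, defn = event_definition()) {
  empty <- data.frame(stay_id = character(0), onset_min = integer(0),
                      end_min = integer(0), stringsAsFactors = FALSE)
  n <- nrow(series)
  W <- defn$window_len
  if (n < W) return(empty)
  b <- below_threshold(series, defn)
  wsum <- cumsum(b)
  wsum <- wsum - c(rep(0L, W), head(wsum, n - W))   # below count per window start
  qual <- which(wsum[W:n] >= defn$min_below)        # 1-based start positions
  if (length(qual) == 0) return(empty)
  # minutes covered by any qualifying window, via a difference array
  delta <- integer(n + 1L)
  delta[qual] <- delta[qual] + 1L
  ends <- pmin(qual + W, n + 1L)
  for (e in ends) delta[e] <- delta[e] - 1L
  covered <- cumsum(delta[seq_len(n)]) > 0L
  # candidate sub-threshold periods: below minutes inside qualifying windows
  periods <- runs_of(covered & b)
  # merge periods separated by <= merge_gap_max minutes
  merged <- periods[1, , drop = FALSE]
  if (nrow(periods) > 1) {
    for (i in 2:nrow(periods)) {
      gap <- periods$start[i] - merged$end[nrow(merged)] - 1L
      if (gap <= defn$merge_gap_max) {
        merged$end[nrow(merged)] <- periods$end[i]
      } else {
        merged <- rbind(merged, periods[i, ])
      }
    }
  }
  data.frame(stay_id = rep(attr(series, "stay_id") %||% NA_character_,
                           nrow(merged)),
             onset_min = merged$start, end_min = merged$end,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

intervention_types <- function() c("vasopressor", "crystalloid_bolus",
                                   "prbc_transfusion")

#' Classify subjects into hypotension / non-hypotension / excluded
#'
#' A subject with at least one detected event belongs to the hypotension
#' group, keyed on the first event only; a subject with no events is
#' non-hypotensive. A hypotension-group subject is excluded when any
#' vasopressor, crystalloid bolus, or packed red-cell transfusion was given
#' within the two hours before the first-event onset (an intervention
#' exactly 120 minutes, or zero minutes, before the onset counts; one 121
#' or more minutes before does not).
#'
#' @param subjects data frame with `subject_id, stay_id, admission_datetime`
#'   (one row per stay).
#' @param events data frame of detected events (`stay_id, onset_min,
#'   end_min`), e.g. rows bound from [detect_hypotension_events()].
#' @param interventions data frame `subject_id, stay_id, minute, type`; an
#'   intervention referencing an unknown stay is an error.
#' @param exclusion_window_min exclusion lookback, minutes (default 120).
#' @return Data frame `subject_id, group, first_stay_id, first_onset_min,
#'   exclusion_reason` with `group` in `{hypotension, non-hypotension,
#'   excluded}`.
#' @export
classify_subjects <- function(subjects, events, interventions = NULL,
                              exclusion_window_min = 120L) {
  if (!is.null(interventions) && nrow(interventions) > 0) {
    unknown <- setdiff(interventions$stay_id, subjects$stay_id)
    if (length(unknown) > 0)
      stop("intervention references unknown stay: ",
           paste(unknown, collapse = ", "))
  }
  out <- lapply(split(subjects, subjects$subject_id), function(ss) {
    ev <- events[events$stay_id %in% ss$stay_id, , drop = FALSE]
    if (nrow(ev) == 0) {
      return(data.frame(subject_id = ss$subject_id[1], group = "non-hypotension",
                        first_stay_id = NA_character_,
                        first_onset_min = NA_integer_,
                        exclusion_reason = NA_character_,
                        stringsAsFactors = FALSE))
    }
    # first event across the subject's stays, by absolute time
    adm <- as.numeric(ss$admission_datetime[match(ev$stay_id, ss$stay_id)])
    first <- ev[order(adm + 60 * ev$onset_min), , drop = FALSE][1, ]
    reason <- NA_character_
    grp <- "hypotension"
    if (!is.null(interventions) && nrow(interventions) > 0) {
      iv <- interventions[interventions$stay_id == first$stay_id &
                            interventions$type %in% intervention_types(), ,
                          drop = FALSE]
      gap <- first$onset_min - iv$minute
      hit <- which(gap >= 0 & gap <= exclusion_window_min)
      if (length(hit) > 0) {
        grp <- "excluded"
        reason <- sprintf("%s %d min before first event",
                          iv$type[hit[1]], gap[hit[1]])
      }
    }
    data.frame(subject_id = ss$subject_id[1], group = grp,
               first_stay_id = first$stay_id,
               first_onset_min = first$onset_min,
               exclusion_reason = reason, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id), ]
}

#' Time to first hypotension event: summary statistics
#'
#' Summarizes, over the hypotension group only, the minutes from ICU
#' admission (minute 0 of the stay) to the first-event onset.
#'
#' @param assignments output of [classify_subjects()].
#' @return List `mean, sd, median, iqr, n` (sd is `NA` for a single
#'   subject).
#' @export
time_to_first_event_stats <- function(assignments) {
  t <- assignments$first_onset_min[assignments$group == "hypotension"]
  if (length(t) == 0) stop("no hypotension-group subjects")
  list(mean = mean(t),
       sd = if (length(t) > 1) sd(t) else NA_real_,
       median = median(t),
       iqr = if (length(t) > 1) IQR(t) else 0,
       n = length(t))
}
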