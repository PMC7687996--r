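#' Construct a vital-sign series for one ICU stay
#'
#' A `vital_series` is a data frame on a regular, 0-based, 1-minute grid with
#' one column per monitored channel: heart rate (`hr`, beats/min),
#' respiratory rate (`rr`, breaths/min), pulse oximetry (`spo2`, %),
#' systolic, diastolic and mean arterial pressure (`sbp`, `dbp`, `map`,
#' mmHg). Any value may be missing (`NA`) at any minute. Stay identity and
#' the admission timestamp travel as attributes; minute 0 is the admission
#' minute.
#'
#' @param minute integer vector of minute indices (0-based). Must be strictly
#'   increasing; gaps are filled with explicitly-missing minutes so the
#'   result is always a contiguous unit-step grid starting at 0.
#' @param hr,rr,spo2,sbp,dbp,map numeric channel values, `NA` for missing.
#' @param subject_id,stay_id identifiers.
#' @param admission admission datetime (`POSIXct`).
#' @return A data frame of class `vital_series`.
#' @export
vital_series <- function(minute, hr, rr, spo2, sbp, dbp, map,
                         subject_id, stay_id,
                         admission = as.POSIXct("2026-01-01", tz = "UTC")) {
  minute <- as.integer(minute)
  if (anyNA(minute)) stop("minute indices must not be missing")
  if (any(duplicated(minute))) stop("duplicate minute index in vital series")
  if (is.unsorted(minute, strictly = TRUE)) stop("minute indices must be strictly increasing")
  if (any(minute < 0L)) stop("minute indices must be >= 0")
  df <- data.frame(minute = minute, hr = hr, rr = rr, spo2 = spo2,
                   sbp = sbp, dbp = dbp, map = map)
  # regularize: contiguous grid 0..max with explicit missing minutes
  grid <- 0:max(minute)
  if (length(grid) != nrow(df) || any(df$minute != grid)) {
    full <- data.frame(minute = grid)
    df <- merge(full, df, by = "minute", all.x = TRUE, sort = TRUE)
  }
  structure(df,
            class = c("vital_series", "data.frame"),
            subject_id = subject_id, stay_id = stay_id,
            admission = admission)
}

#' @exportS3Method base::print
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series> stay %s, subject %s, %d min, admitted %s\n",
              attr(x, "stay_id"), attr(x, "subject_id"), nrow(x),
              format(attr(x, "admission"))))
  miss <- vapply(vital_channels(), function(ch) mean(is.na(x[[ch]])), numeric(1))
  cat("missingness:", paste(sprintf("%s %.1f%%", names(miss), 100 * miss),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Names of the monitored channels
#' @return Character vector of channel column names.
#' @export
vital_channels <- function() c("hr", "rr", "spo2", "sbp", "dbp", "map")

stay_id_of <- function(series) attr(series, "stay_id")
subject_id_of <- function(series) attr(series, "subject_id")
admission_of <- function(series) attr(series, "admission")

# rebuild a vital_series with new channel data, same identity
with_channels <- function(series, data) {
  vital_series(series$minute, data$hr, data$rr, data$spo2,
               data$sbp, data$dbp, data$map,
               subject_id = subject_id_of(series),
               stay_id = stay_id_of(series),
               admission = admission_of(series))
}
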