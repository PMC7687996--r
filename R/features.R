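#' Feature-engineering configuration
#'
#' Features are computed per channel on rolling windows that end at the
#' current minute, inclusive (`[t - W + 1, t]`), one step per minute, for
#' every window length in `window_lengths`. Each channel-window pair yields
#' the summary statistics (mean, sample variance, min, max, lower and upper
#' quartile, median; type-7 linear-interpolation quantiles), the magnitudes
#' of the `dft_coeffs` lowest non-constant discrete Fourier coefficients of
#' the demeaned (mean-filled) window, and the exponentially weighted moving
#' average of the window's present values. A window with fewer than
#' `min_completeness` of its minutes present is skipped; a feature row
#' exists for a minute only when every required window is present.
#'
#' @param window_lengths window lengths in minutes (default 5, 10, 30, 60).
#' @param dft_coeffs number of leading non-constant DFT magnitudes retained
#'   per channel-window (default 5).
#' @param ewma_alpha EWMA decay in (0, 1] (default 0.3).
#' @param min_completeness minimum fraction of non-missing minutes per
#'   window (default 0.5).
#' @param channels channels to featurize (default all six).
#' @return List of class `feature_config`.
#' @export
feature_config <- function(window_lengths = c(5L, 10L, 30L, 60L),
                           dft_coeffs = 5L, ewma_alpha = 0.3,
                           min_completeness = 0.5,
                           channels = vital_channels()) {
  if (any(window_lengths < 2)) stop("window lengths must be >= 2")
  if (ewma_alpha <= 0 || ewma_alpha > 1) stop("ewma_alpha must lie in (0, 1]")
  if (min_completeness <= 0 || min_completeness > 1)
    stop("min_completeness must lie in (0, 1]")
  structure(list(window_lengths = as.integer(sort(window_lengths)),
                 dft_coeffs = as.integer(dft_coeffs),
                 ewma_alpha = ewma_alpha,
                 min_completeness = min_completeness,
                 channels = channels),
            class = "feature_config")
}

window_stat_names <- function() c("mean", "var", "min", "max", "q1", "median", "q3")

#' Summary statistics of one window
#'
#' Reference implementation of the per-window statistics, computed over the
#' present values only. Returns `NULL` when the fraction present falls below
#' `min_completeness` (the window is skipped). Variance is the sample
#' variance (n - 1 denominator); quartiles use linear interpolation between
#' order statistics.
#'
#' @param values numeric window values (may contain `NA`).
#' @param config a [feature_config()] supplying `min_completeness`.
#' @return Named numeric vector `mean, var, min, max, q1, median, q3`, or
#'   `NULL` if the window is too incomplete.
#' @export
window_stats <- function(values, config = feature_config()) {
  ok <- values[!is.na(values)]
  if (length(ok) / length(values) < config$min_completeness) return(NULL)
  q <- quantile(ok, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(ok),
    var = if (length(ok) > 1) stats::var(ok) else NA_real_,
    min = min(ok), max = max(ok),
    q1 = q[1], median = q[2], q3 = q[3])
}

#' DFT magnitude features of one window
#'
#' Missing values are filled with the window mean, the mean is subtracted
#' (so filled minutes contribute zero), and the magnitudes of the `n_coef`
#' lowest non-constant discrete Fourier coefficients are returned. With
#' `n_coef = length(values) - 1` the full (non-DC) spectrum is returned and
#' Parseval's identity holds: `sum(mag^2) / N` equals the demeaned window's
#' sum of squares.
#'
#' @param values numeric window values (may contain `NA`; at least one
#'   present).
#' @param n_coef number of coefficients retained.
#' @return Named numeric vector `dft1 ... dft<n_coef>`.
#' @export
dft_features <- function(values, n_coef = 5L) {
  m <- mean(values, na.rm = TRUE)
  y <- ifelse(is.na(values), 0, values - m)
  N <- length(y)
  X <- fft(y)
  k <- seq_len(n_coef)
  mags <- Mod(X)[(k %% N) + 1L]
  setNames(mags, paste0("dft", k))
}

#' Exponentially weighted moving average
#'
#' Recursive smoother over the present values in chronological order:
#' `s_t = alpha * x_t + (1 - alpha) * s_{t-1}`, initialized at the first
#' present value. Returns the smoothed value at the window end. `alpha = 1`
#' degenerates to the last present value.
#'
#' @param values numeric values (may contain `NA`; at least one present).
#' @param alpha decay in (0, 1].
#' @return The final smoothed value.
#' @export
ewma <- function(values, alpha = 0.3) {
  ok <- values[!is.na(values)]
  if (length(ok) == 0) stop("ewma needs at least one present value")
  s <- ok[1]
  for (v in ok[-1]) s <- alpha * v + (1 - alpha) * s
  s
}

feature_names_for <- function(config) {
  unlist(lapply(config$channels, function(ch)
    unlist(lapply(config$window_lengths, function(W)
      paste(ch, paste0("w", W),
            c(window_stat_names(),
              paste0("dft", seq_len(config$dft_coeffs)), "ewma"),
            sep = "_")))),
    use.names = FALSE)
}

#' Build the per-minute feature matrix for one stay
#'
#' Computes every configured channel-window feature for each minute of the
#' series using a compiled rolling kernel, and keeps the minutes at which
#' all required windows are available and sufficiently complete. Features
#' at minute t depend only on minutes up to t (causal).
#'
#' @param series a cleaned, imputed [vital_series()].
#' @param config a [feature_config()].
#' @param minutes optional integer vector restricting the output to these
#'   end minutes (0-based); rows that fail the completeness rule are still
#'   dropped.
#' @return Data frame `stay_id, end_minute` followed by one column per
#'   feature, in deterministic order.
#' @export
build_feature_matrix <- function(series, config = feature_config(),
                                 minutes = NULL) {
  n <- nrow(series)
  K <- config$dft_coeffs
  cols <- vector("list", length(config$channels) * length(config$window_lengths))
  idx <- 1L
  for (ch in config$channels) {
    x <- as.numeric(series[[ch]])
    for (W in config$window_lengths) {
      m <- cpp_roll_features(x, W, K, config$ewma_alpha, config$min_completeness)
      block <- m[, seq_len(8L + K), drop = FALSE]   # drop the count column
      colnames(block) <- paste(ch, paste0("w", W),
                               c(window_stat_names(),
                                 paste0("dft", seq_len(K)), "ewma"),
                               sep = "_")
      cols[[idx]] <- block
      idx <- idx + 1L
    }
  }
  mat <- do.call(cbind, cols)
  keep <- stats::complete.cases(mat)
  if (!is.null(minutes)) keep <- keep & series$minute %in% minutes
  out <- data.frame(stay_id = rep(stay_id_of(series) %||% NA_character_, sum(keep)),
                    end_minute = series$minute[keep],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat[keep, , drop = FALSE]))
}

feature_columns <- function(features) {
  setdiff(names(features), c("stay_id", "end_minute", "label",
                             "lead_time_min", "split", "subject_id"))
}
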