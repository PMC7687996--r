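# Independent brute-force oracles and small fixture builders.
# These deliberately use naive loops, not the package's vectorized code.

# event-detection oracle: enumerate every 10-min window, apply the
# >= min_below rule, take the below-threshold minutes covered by a
# qualifying window as the sub-threshold periods, merge gaps <= 2 min,
# report each merged period's first and last minute.
oracle_detect <- function(b, window_len = 10L, min_below = 5L,
                          merge_gap_max = 2L) {
  n <- length(b)
  covered <- rep(FALSE, n)
  if (n >= window_len) {
    for (s in 1:(n - window_len + 1L)) {
      if (sum(b[s:(s + window_len - 1L)]) >= min_below)
        covered[s:(s + window_len - 1L)] <- TRUE
    }
  }
  covered <- covered & b
  if (!any(covered)) return(data.frame(onset_min = integer(0),
                                       end_min = integer(0)))
  # maximal covered periods (0-based)
  periods <- list()
  i <- 1L
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1L]) j <- j + 1L
      periods[[length(periods) + 1L]] <- c(i - 1L, j - 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge gaps <= merge_gap_max
  merged <- list(periods[[1]])
  for (p in periods[-1]) {
    last <- merged[[length(merged)]]
    if (p[1] - last[2] - 1L <= merge_gap_max) {
      merged[[length(merged)]] <- c(last[1], p[2])
    } else merged[[length(merged) + 1L]] <- p
  }
  onset <- vapply(merged, `[`, integer(1), 1L)
  endm <- vapply(merged, `[`, integer(1), 2L)
  data.frame(onset_min = onset, end_min = endm)
}

# AUROC oracle: exhaustive pairwise concordance, ties half credit
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPRC oracle: explicit threshold enumeration over distinct scores
oracle_auprc <- function(scores, y) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(y == 1)
  area <- 0; prev_recall <- 0
  for (t in th) {
    sel <- scores >= t
    recall <- sum(y[sel] == 1) / P
    precision <- mean(y[sel] == 1)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# a vital_series realizing a given below-threshold pattern
series_from_pattern <- function(b, stay_id = "T1") {
  n <- length(b)
  vital_series(0:(n - 1L),
               hr = rep(80, n), rr = rep(16, n), spo2 = rep(97, n),
               sbp = ifelse(b, 80, 120), dbp = ifelse(b, 45, 70),
               map = ifelse(b, 55, 85),
               subject_id = stay_id, stay_id = stay_id)
}

# a fully explicit small series from channel vectors (defaults normal)
make_series <- function(n, sbp = rep(120, n), map = rep(85, n),
                        hr = rep(80, n), rr = rep(16, n),
                        spo2 = rep(97, n), dbp = rep(70, n),
                        stay_id = "T1",
                        admission = as.POSIXct("2026-01-01", tz = "UTC")) {
  vital_series(0:(n - 1L), hr, rr, spo2, sbp, dbp, map,
               subject_id = stay_id, stay_id = stay_id,
               admission = admission)
}
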