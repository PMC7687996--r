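#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted half. Computed from mid-ranks, so it
#' is exact and invariant under strictly monotone score transforms.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1, logical, or a factor whose second
#'   level is positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) stop("auroc needs both classes present")
  r <- rank(scores)               # mid-ranks: ties get half credit
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.character(labels)) labels <- as.integer(labels == "positive")
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  as.integer(labels)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (trapezoid-free) average precision: scores are swept from high
#' to low, grouped at distinct values (ties enter together), and the area
#' accumulates precision times the recall increment at each threshold. For
#' uninformative constant scores the value equals the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  P <- sum(y == 1)
  if (P == 0) stop("auprc needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- y[o]
  grp_end <- cumsum(rle(s)$lengths)     # last index at each distinct score
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Brier score and reliability bins
#'
#' Brier score = mean squared difference between predicted score and binary
#' outcome. Reliability bins are `n_bins` equal-width bins over \[0, 1\]
#' with mean predicted score, observed event frequency and count per bin.
#'
#' @inheritParams auroc
#' @param n_bins number of equal-width bins (default 10).
#' @return List with `brier` and `bins` (data frame `bin_lo, bin_hi,
#'   mean_predicted, observed, n`).
#' @export
calibration <- function(scores, labels, n_bins = 10L) {
  y <- as_binary_labels(labels)
  brier <- mean((scores - y)^2)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- pmin(findInterval(scores, edges, rightmost.closed = TRUE), n_bins)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    idx <- bin == b
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mean_predicted = if (any(idx)) mean(scores[idx]) else NA_real_,
               observed = if (any(idx)) mean(y[idx]) else NA_real_,
               n = sum(idx))
  }))
  list(brier = brier, bins = bins)
}

#' Lead-time-resolved AUROC and AUPRC
#'
#' At each lead time L of the grid, the positive scores are the hypotension
#' stays' risk scores exactly L minutes before their first-event onset and
#' the negative scores are the non-hypotension stays' scores L minutes
#' before their pseudo-onset. When the exact minute is unscored, the
#' nearest scored minute within `tolerance_min` is used. Grid points with
#' fewer than two stays per class are omitted.
#'
#' @param trajectories data frame `stay_id, group, lead_min, score` of
#'   aligned scores (see [align_trajectory()]); `group` is `"hypotension"`
#'   or `"non-hypotension"`.
#' @param grid lead times in minutes (default 0..240 by 5).
#' @param tolerance_min how far the nearest scored minute may be (default 1).
#' @return Data frame `lead_min, auroc, auprc, n_pos, n_neg`.
#' @export
lead_time_curves <- function(trajectories, grid = seq(0, 240, by = 5),
                             tolerance_min = 1L) {
  pick <- function(tr, L) {
    d <- abs(tr$lead_min - L)
    ok <- which(d <= tolerance_min)
    if (length(ok) == 0) return(NA_real_)
    tr$score[ok[order(d[ok], tr$lead_min[ok])][1]]
  }
  by_stay <- split(trajectories, trajectories$stay_id)
  grp <- vapply(by_stay, function(tr) tr$group[1], character(1))
  rows <- lapply(grid, function(L) {
    v <- vapply(by_stay, pick, numeric(1), L = L)
    pos <- v[grp == "hypotension" & !is.na(v)]
    neg <- v[grp == "non-hypotension" & !is.na(v)]
    if (length(pos) < 2 || length(neg) < 2) return(NULL)
    sc <- c(pos, neg)
    y <- c(rep(1L, length(pos)), rep(0L, length(neg)))
    data.frame(lead_min = L, auroc = auroc(sc, y), auprc = auprc(sc, y),
               n_pos = length(pos), n_neg = length(neg))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(lead_min = numeric(0), auroc = numeric(0),
                      auprc = numeric(0), n_pos = integer(0),
                      n_neg = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Patient-level AUPRC
#'
#' Aggregates each stay's risk scores to a single value (the maximum over
#' the evaluated span) and computes the AUPRC over stays, labelling
#' hypotension stays positive. `mode = "whole-stay"` uses every scored
#' minute of the stay; `mode = "random-hour"` uses a seeded random
#' contiguous 60-minute span within the scored range.
#'
#' @param scores data frame `stay_id, minute, score`.
#' @param groups data frame `stay_id, group`.
#' @param mode `"whole-stay"` or `"random-hour"`.
#' @param seed integer seed for the random-hour draw.
#' @return AUPRC over stays.
#' @export
patient_level_auprc <- function(scores, groups,
                                mode = c("whole-stay", "random-hour"),
                                seed = 1L) {
  mode <- match.arg(mode)
  by_stay <- split(scores, scores$stay_id)
  set.seed(seed)
  agg <- vapply(by_stay, function(d) {
    if (mode == "random-hour") {
      lo <- min(d$minute)
      hi <- max(d$minute)
      start <- if (hi - lo <= 59) lo else
        as.integer(round(runif(1, lo, hi - 59)))
      d <- d[d$minute >= start & d$minute <= start + 59L, , drop = FALSE]
    }
    max(d$score)
  }, numeric(1))
  grp <- groups$group[match(names(agg), groups$stay_id)]
  keep <- !is.na(grp)
  auprc(agg[keep], as.integer(grp[keep] == "hypotension"))
}
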