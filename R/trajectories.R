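#' Align one stay's risk scores on an event (or pseudo-event) origin
#'
#' Re-indexes per-minute scores by lead time: the score at lead L is the
#' score at minute `origin - L`. Minutes after the origin are dropped;
#' unscored minutes stay absent. An origin before the first scored minute
#' yields an empty alignment.
#'
#' @param scores data frame `minute, score` for one stay.
#' @param origin_minute the alignment origin (first-event onset for
#'   hypotension stays, pseudo-onset otherwise).
#' @return Data frame `lead_min, score`, sorted by increasing lead.
#' @export
align_trajectory <- function(scores, origin_minute) {
  lead <- origin_minute - scores$minute
  keep <- lead >= 0
  out <- data.frame(lead_min = lead[keep], score = scores$score[keep])
  out[order(out$lead_min), , drop = FALSE]
}

#' Build aligned trajectories for a set of stays
#'
#' @param scores data frame `stay_id, minute, score`.
#' @param origins data frame `stay_id, origin_min, group`.
#' @return Data frame `stay_id, group, lead_min, score`.
#' @export
build_trajectories <- function(scores, origins) {
  rows <- lapply(seq_len(nrow(origins)), function(i) {
    d <- scores[scores$stay_id == origins$stay_id[i], , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    al <- align_trajectory(d, origins$origin_min[i])
    if (nrow(al) == 0) return(NULL)
    cbind(data.frame(stay_id = origins$stay_id[i], group = origins$group[i],
                     stringsAsFactors = FALSE),
          al)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Event-aligned group mean trajectories with 95% confidence intervals
#'
#' At each lead time of the grid and for each group, the mean risk score
#' over contributing stays with a normal-approximation 95% confidence
#' interval (mean plus or minus 1.96 standard errors) and the number of
#' contributing stays. Lead times with fewer than two stays in a group are
#' omitted for that group.
#'
#' @param trajectories data frame `stay_id, group, lead_min, score` (see
#'   [build_trajectories()]).
#' @param grid lead times in minutes (default 0..240 by 5).
#' @return Data frame `group, lead_min, mean, ci_lo, ci_hi, n`.
#' @export
group_summary <- function(trajectories, grid = seq(0, 240, by = 5)) {
  rows <- list()
  for (g in unique(trajectories$group)) {
    tg <- trajectories[trajectories$group == g, ]
    for (L in grid) {
      v <- tg$score[tg$lead_min == L]
      if (length(v) < 2) next
      se <- sd(v) / sqrt(length(v))
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, lead_min = L, mean = mean(v),
                   ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se,
                   n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
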