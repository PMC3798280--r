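# Scoring predicted binding events against known positions.

# Comparator for partial matchings: more pairs wins; then smaller total
# distance; then lexicographically smaller (prediction, truth) pair list.
.better_matching <- function(a, b) {
  if (a$n != b$n) return(a$n > b$n)
  if (abs(a$dist - b$dist) > 1e-9) return(a$dist < b$dist)
  pa <- a$pairs; pb <- b$pairs
  k <- min(nrow(pa), nrow(pb))
  if (k > 0) {
    for (i in seq_len(k)) {
      if (pa$pred[i] != pb$pred[i]) return(pa$pred[i] < pb$pred[i])
      if (pa$truth[i] != pb$truth[i]) return(pa$truth[i] < pb$truth[i])
    }
  }
  FALSE
}

#' Match predicted events to true events
#'
#' Finds the optimal one-to-one matching between predictions and truths on
#' the bipartite graph of pairs closer than `tolerance`: the matching with
#' the largest number of pairs, breaking ties by the smallest total
#' distance, then by lexicographic pair order. Solved exactly by dynamic
#' programming over subsets of truths.
#'
#' @param predictions Predicted event positions (bp).
#' @param truths True/annotated event positions (bp).
#' @param tolerance Identification tolerance (bp): a pair is admissible when
#'   its distance is strictly less than `tolerance`.
#' @return A list of class `"match_result"`: `pairs` (data.frame `pred`,
#'   `truth`, `distance` with 1-based indices), `unmatched_truths`,
#'   `unmatched_predictions`, `tolerance`.
#' @export
match_events <- function(predictions, truths, tolerance = 20) {
  stopifnot(tolerance > 0)
  n <- length(predictions)
  m <- length(truths)
  if (m > 20L) stop("too many truths for exact matching (", m, " > 20)")
  dist_mat <- if (n > 0 && m > 0) {
    abs(outer(predictions, truths, `-`))
  } else {
    matrix(numeric(0), n, m)
  }
  memo <- new.env(parent = emptyenv())
  empty <- list(n = 0L, dist = 0,
                pairs = data.frame(pred = integer(0), truth = integer(0),
                                   distance = numeric(0)))
  solve <- function(i, mask) {
    if (i > n) return(empty)
    key <- paste0(i, "_", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # option: leave prediction i unmatched
    best <- solve(i + 1L, mask)
    for (t in seq_len(m)) {
      bit <- bitwShiftL(1L, t - 1L)
      if (bitwAnd(mask, bit) > 0) next
      d <- dist_mat[i, t]
      if (d >= tolerance) next
      sub <- solve(i + 1L, bitwOr(mask, bit))
      cand <- list(
        n = sub$n + 1L,
        dist = sub$dist + d,
        pairs = rbind(data.frame(pred = i, truth = t, distance = d),
                      sub$pairs)
      )
      if (.better_matching(cand, best)) best <- cand
    }
    memo[[key]] <- best
    best
  }
  res <- solve(1L, 0L)
  structure(list(
    pairs = res$pairs,
    unmatched_truths = setdiff(seq_len(m), res$pairs$truth),
    unmatched_predictions = setdiff(seq_len(n), res$pairs$pred),
    tolerance = tolerance
  ), class = "match_result")
}

#' Region-level sensitivity
#'
#' The fraction of regions for which every true event was identified (no
#' unmatched truth), the standard sensitivity definition for joint binding
#' events.
#'
#' @param match_results A list of `"match_result"` objects, one per region.
#' @return Fraction in \[0, 1\].
#' @export
sensitivity <- function(match_results) {
  stopifnot(length(match_results) >= 1)
  mean(vapply(match_results,
              function(m) length(m$unmatched_truths) == 0L, TRUE))
}

#' Fraction of predictions matched
#'
#' A direct positive-predictive-value reading: the proportion of predicted
#' events that were matched to a true event.
#'
#' @param match_results A list of `"match_result"` objects.
#' @return Fraction in \[0, 1\].
#' @export
ppv_matched <- function(match_results) {
  n_pred <- sum(vapply(match_results, function(m) {
    nrow(m$pairs) + length(m$unmatched_predictions)
  }, 0L))
  if (n_pred == 0L) return(NA_real_)
  sum(vapply(match_results, function(m) nrow(m$pairs), 0L)) / n_pred
}

#' Mean number of predicted events per condition cell
#'
#' Summarizes the number of predictions per region by simulation cell with
#' a normal-approximation confidence interval — the display used to judge
#' positive predictive value when each region holds a known number of true
#' events.
#'
#' @param fits_df A `data.frame` with one row per fitted region, a numeric
#'   column `G` (selected number of events) and grouping columns.
#' @param by Names of the grouping columns.
#' @param conf Confidence level.
#' @return A `data.frame` with `mean_G`, `se`, `lo`, `hi`, `n_regions` per
#'   cell.
#' @export
prediction_count_profile <- function(fits_df, by = c("distance", "depth"),
                                     conf = 0.95) {
  stopifnot(nrow(fits_df) >= 1, all(by %in% names(fits_df)))
  z <- qnorm(1 - (1 - conf) / 2)
  agg <- aggregate(fits_df$G, fits_df[by], function(g) {
    c(mean = mean(g), se = sd(g) / sqrt(length(g)), n = length(g))
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  out$se[is.na(out$se)] <- 0
  out$mean_G <- out$mean
  out$lo <- out$mean - z * out$se
  out$hi <- out$mean + z * out$se
  out$n_regions <- out$n
  out[, c(by, "mean_G", "se", "lo", "hi", "n_regions")]
}

#' Per-prediction resolution
#'
#' Resolution of a predicted event is its minimum distance to any annotated
#' position.
#'
#' @param predictions Predicted positions (bp).
#' @param truths Annotated positions (bp); must be non-empty.
#' @return Numeric vector, one value per prediction.
#' @export
resolution <- function(predictions, truths) {
  if (length(truths) == 0L) stop("truths must be non-empty")
  vapply(predictions, function(p) min(abs(p - truths)), 0)
}

#' Differential occupancy across two conditions
#'
#' Matches the event sets of two conditions one-to-one (as in
#' [match_events()]): matched events are common, unmatched ones are
#' condition-specific. If per-event region identifiers are supplied, a
#' per-region cross-tabulation of event counts across the two conditions is
#' attached.
#'
#' @param events_a,events_b Event positions under conditions A and B.
#' @param tolerance Matching tolerance (bp).
#' @param regions_a,regions_b Optional region identifier per event.
#' @return A list: `common` (data.frame of matched positions and distance),
#'   `a_specific`, `b_specific` (positions), `counts` (named totals), and
#'   `region_crosstab` when region identifiers were given.
#' @export
differential_occupancy <- function(events_a, events_b, tolerance = 20,
                                   regions_a = NULL, regions_b = NULL) {
  mr <- match_events(events_a, events_b, tolerance)
  common <- data.frame(
    pos_a = events_a[mr$pairs$pred],
    pos_b = events_b[mr$pairs$truth],
    distance = mr$pairs$distance
  )
  out <- list(
    common = common,
    a_specific = events_a[mr$unmatched_predictions],
    b_specific = events_b[mr$unmatched_truths],
    counts = c(common = nrow(common),
               a_specific = length(mr$unmatched_predictions),
               b_specific = length(mr$unmatched_truths))
  )
  if (!is.null(regions_a) || !is.null(regions_b)) {
    regions <- union(unique(regions_a), unique(regions_b))
    na <- vapply(regions, function(r) sum(regions_a == r), 0L)
    nb <- vapply(regions, function(r) sum(regions_b == r), 0L)
    out$region_crosstab <- table(events_A = na, events_B = nb)
  }
  out
}
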