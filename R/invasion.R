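# Invasion / truncation probabilities for single-end reads.
#
# Setting: two binding events d bp apart; a DNA fragment generated from the
# first event (length L from the library-size law, leftmost uniform over the
# L covering start positions); single-end sequencing keeps one random end,
# which analysis extends by a fixed estimate Lhat of the library size in the
# read's 3' direction.
#
#   invasion   = the true fragment covers only the first event, but the
#                extended read covers both (over-extension).
#   truncation = the true fragment covers both events, but the extended
#                read covers exactly one (under-extension).
#
# Both probabilities are available by exhaustive enumeration over the
# discrete (L, leftmost, end-choice) space — exact under the generative
# model — and by Monte-Carlo sampling, with the enumeration as reference.

#' Invasion / truncation setup
#'
#' @param d Distance between the two event positions (bp, >= 1).
#' @param length_dist Library-size distribution (`"fld"`).
#' @param est_size Fixed extension length Lhat used by the single-end
#'   analysis (bp); defaults to the rounded mean library size.
#' @param sd_scale Multiplier `a` applied to the spread of the library-size
#'   distribution: lengths are rescaled about the distribution mean by `a`
#'   and re-truncated to >= 1 bp, keeping the mean (approximately) fixed.
#' @return An `"inv_setup"` list with the scaled distribution attached.
#' @export
invasion_setup <- function(d, length_dist = default_length_dist(),
                           est_size = NULL, sd_scale = 1) {
  stopifnot(d >= 1, sd_scale > 0)
  if (is.null(est_size)) est_size <- round(.fld_mean(length_dist))
  stopifnot(est_size >= 1)
  structure(list(d = as.integer(d), length_dist = length_dist,
                 est_size = as.integer(est_size), sd_scale = sd_scale,
                 scaled_dist = scale_length_sd(length_dist, sd_scale)),
            class = "inv_setup")
}

#' Rescale the spread of a length distribution
#'
#' Maps each length `L` to `round(m + a * (L - m))` where `m` is the
#' distribution mean, floors at 1 bp, and aggregates collided support
#' points. `a = 1` returns the input unchanged.
#'
#' @param fld An `"fld"` object.
#' @param a Spread multiplier (> 0).
#' @return An `"fld"` object with standard deviation scaled by ~`a`.
#' @export
scale_length_sd <- function(fld, a) {
  if (a == 1) return(fld)
  m <- .fld_mean(fld)
  new_support <- pmax(as.integer(round(m + a * (fld$support - m))), 1L)
  agg <- rowsum(fld$pmf, new_support)
  fragment_length_dist(as.integer(rownames(agg)), agg[, 1L])
}

# Classify one batch of draws. Returns logical vectors (invasion,
# truncation) for fragments with length L, leftmost l, forward end-choice
# flag. mu1 = 0 without loss of generality, mu2 = d.
.classify_inv_trunc <- function(L, l, fwd, d, Lhat) {
  right <- l + L - 1L
  fwd <- rep_len(fwd, length(right))
  covers2 <- right >= d             # fragment always covers mu1 by design
  ext_lo <- ifelse(fwd, l, right - Lhat + 1L)
  ext_hi <- ifelse(fwd, l + Lhat - 1L, right)
  ext1 <- ext_lo <= 0L & ext_hi >= 0L
  ext2 <- ext_lo <= d & ext_hi >= d
  list(invasion = !covers2 & ext1 & ext2,
       truncation = covers2 & xor(ext1, ext2))
}

#' Exact invasion/truncation probabilities by enumeration
#'
#' Total-probability sum over the discrete space of (length, leftmost
#' position, sequenced end): lengths weighted by the scaled library-size
#' pmf, the `L` covering leftmost positions each with probability `1/L`,
#' and each end with probability 1/2.
#'
#' @param setup An `"inv_setup"`.
#' @return Named numeric vector `c(invasion, truncation)`.
#' @export
enumerate_inv_trunc <- function(setup) {
  d <- setup$d
  Lhat <- setup$est_size
  fld <- setup$scaled_dist
  inv <- 0
  trunc <- 0
  for (k in seq_along(fld$support)) {
    L <- fld$support[k]
    l <- seq.int(-L + 1L, 0L)       # mu1 = 0
    cl <- .classify_inv_trunc(L, l, fwd = TRUE, d = d, Lhat = Lhat)
    cr <- .classify_inv_trunc(L, l, fwd = FALSE, d = d, Lhat = Lhat)
    w <- fld$pmf[k] / L / 2
    inv <- inv + w * (sum(cl$invasion) + sum(cr$invasion))
    trunc <- trunc + w * (sum(cl$truncation) + sum(cr$truncation))
  }
  c(invasion = inv, truncation = trunc)
}

.sample_inv_trunc <- function(setup, n_mc, seed) {
  set.seed(seed)
  fld <- setup$scaled_dist
  L <- .sample_lengths(fld, n_mc)
  l <- -L + 1L + floor(runif(n_mc) * L)
  fwd <- runif(n_mc) < 0.5
  .classify_inv_trunc(L, l, fwd, setup$d, setup$est_size)
}

#' Monte-Carlo invasion probability
#'
#' @param setup An `"inv_setup"`.
#' @param n_mc Number of simulated fragments.
#' @param seed Integer seed.
#' @return A list with `p` (frequency) and `se` (binomial standard error).
#' @export
invasion_probability <- function(setup, n_mc = 1e5, seed = 1L) {
  stopifnot(n_mc >= 1)
  cl <- .sample_inv_trunc(setup, n_mc, seed)
  p <- mean(cl$invasion)
  list(p = p, se = sqrt(p * (1 - p) / n_mc))
}

#' Monte-Carlo truncation probability
#'
#' @inheritParams invasion_probability
#' @return A list with `p` and `se`.
#' @export
truncation_probability <- function(setup, n_mc = 1e5, seed = 1L) {
  stopifnot(n_mc >= 1)
  cl <- .sample_inv_trunc(setup, n_mc, seed)
  p <- mean(cl$truncation)
  list(p = p, se = sqrt(p * (1 - p) / n_mc))
}

#' Invasion/truncation probability curves
#'
#' Evaluates the probabilities on a full grid of inter-event distances and
#' spread multipliers, by exact enumeration and (optionally) Monte Carlo.
#'
#' @param d_grid Distances (bp).
#' @param sd_scales Spread multipliers `a`.
#' @param length_dist Library-size distribution.
#' @param est_size Extension length Lhat (default: mean library size).
#' @param n_mc Monte-Carlo draws per cell (0 to skip MC columns).
#' @param seed Integer seed.
#' @return A tidy `data.frame` with columns `d`, `a`, `invasion_p`,
#'   `truncation_p` (enumeration) and, when `n_mc > 0`, `invasion_mc`,
#'   `truncation_mc`, `invasion_se`, `truncation_se`.
#' @export
probability_curve <- function(d_grid, sd_scales = 1,
                              length_dist = default_length_dist(),
                              est_size = NULL, n_mc = 0, seed = 1L) {
  stopifnot(length(d_grid) >= 1, length(sd_scales) >= 1)
  grid <- expand.grid(d = d_grid, a = sd_scales)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    setup <- invasion_setup(grid$d[i], length_dist, est_size, grid$a[i])
    ex <- enumerate_inv_trunc(setup)
    row <- data.frame(d = grid$d[i], a = grid$a[i],
                      invasion_p = ex[["invasion"]],
                      truncation_p = ex[["truncation"]])
    if (n_mc > 0) {
      cl <- .sample_inv_trunc(setup, n_mc, seed + i)
      pi_ <- mean(cl$invasion)
      pt_ <- mean(cl$truncation)
      row$invasion_mc <- pi_
      row$truncation_mc <- pt_
      row$invasion_se <- sqrt(pi_ * (1 - pi_) / n_mc)
      row$truncation_se <- sqrt(pt_ * (1 - pt_) / n_mc)
    }
    row
  })
  do.call(rbind, rows)
}
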