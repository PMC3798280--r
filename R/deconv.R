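# Mixture-model deconvolution of one candidate region.
#
# Observation model, per region of width W = end - start:
#   PET fragment (left, right, L), event component at mu:
#       p(left | L, event g) = 1/L  if  left <= mu_g <= right,  else 0
#     (fragment length itself follows the empirical library-size law, which
#      is common to all components and therefore drops from the mixture).
#   PET background: leftmost uniform over the region, density 1/W.
#   SET tag (pos5, strand), event component at mu with shared shift delta,
#   spread sigma and forward-strand probability q:
#       forward: q     * Normal(pos5; mu - delta, sigma^2)
#       reverse: (1-q) * Normal(pos5; mu + delta, sigma^2)
#   SET background: uniform over region times a fair strand coin,
#       (1/W) * (1/2).
# Mixture weights: G event proportions plus one background proportion.

#' Log-density of a PET fragment under one event component
#'
#' A fragment informative for an event must cover it; conditional on its
#' length the leftmost position is uniform over the L start positions that
#' achieve coverage, giving density 1/L on the covering set.
#'
#' @param left,right Fragment bounds, 0-based inclusive.
#' @param mu Event position.
#' @return `log(1/L)` where the fragment covers `mu`, `-Inf` elsewhere.
#'   Vectorized over fragments.
#' @export
pet_log_emission <- function(left, right, mu) {
  L <- right - left + 1
  ifelse(left <= mu & mu <= right, -log(L), -Inf)
}

#' Log-density of the uniform background component
#'
#' @param region One-row region data.frame.
#' @param mode `"pet"` or `"set"`; SET adds the fair strand coin.
#' @return A single log-density value.
#' @export
background_log_emission <- function(region, mode = c("pet", "set")) {
  mode <- match.arg(mode)
  W <- region$end - region$start
  if (W < 1) stop("region width must be >= 1")
  -log(W) + if (mode == "set") log(0.5) else 0
}

#' Log-density of a SET tag under one event component
#'
#' @param pos5 5'-end coordinate(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @param mu Event position.
#' @param delta Shift from event to expected 5' end (bp, > 0).
#' @param sigma Spread of 5' ends (bp, > 0).
#' @param q Forward-strand probability.
#' @return Log-density, vectorized over tags.
#' @export
set_log_emission <- function(pos5, strand, mu, delta, sigma, q = 0.5) {
  if (sigma <= 0) stop("sigma must be > 0")
  fwd <- strand == "+"
  ifelse(fwd,
         log(q) + dnorm(pos5, mu - delta, sigma, log = TRUE),
         log(1 - q) + dnorm(pos5, mu + delta, sigma, log = TRUE))
}

#' Bayesian information criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param p_free Number of free parameters.
#' @param n_obs Number of observations.
#' @return `-2 * loglik + p_free * log(n_obs)`.
#' @export
bic <- function(loglik, p_free, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * loglik + p_free * log(n_obs)
}

#' Initial parameters for the EM fit
#'
#' PET event positions start, under the default `"coverage"` strategy, at
#' the `G` highest mutually separated local maxima of the fragment-coverage
#' profile (summits), the natural starting points for a coverage-based
#' emission; under `"quantile"` they start at `G` evenly spaced quantiles
#' of fragment midpoints (`G = 1` gives the median). SET positions start at
#' evenly spaced quantiles of strand-corrected 5' ends (`pos5 + delta0`
#' forward, `pos5 - delta0` reverse). Weights are uniform over events with
#' a 0.2 background share. Deterministic for given inputs.
#'
#' @param obs Observations (fragments or tags).
#' @param region One-row region data.frame.
#' @param G Number of event components.
#' @param mode `"pet"` or `"set"`.
#' @param delta0 Initial shift, half the expected library size (bp).
#' @param sigma0 Initial 5'-end spread (bp).
#' @param strategy `"coverage"` (PET default) or `"quantile"`.
#' @param min_sep Minimum separation between coverage-summit starts (bp).
#' @return A parameter list (`mu`, `weights`, and for SET `delta`, `sigma`,
#'   `q`).
#' @export
init_params <- function(obs, region, G, mode = c("pet", "set"),
                        delta0 = 100, sigma0 = 30,
                        strategy = c("coverage", "quantile"),
                        min_sep = 100L) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  n <- nrow(obs)
  if (n < G + 1) stop("insufficient reads: ", n, " observations for G = ", G)
  if (mode == "pet" && strategy == "coverage") {
    mu <- .coverage_summits(obs, region, G, min_sep)
  } else {
    centers <- if (mode == "pet") {
      (obs$left + obs$right) / 2
    } else {
      ifelse(obs$strand == "+", obs$pos5 + delta0, obs$pos5 - delta0)
    }
    probs <- if (G == 1L) 0.5 else (2 * seq_len(G) - 1) / (2 * G)
    mu <- as.numeric(quantile(centers, probs = probs, names = FALSE))
  }
  mu <- sort(pmin(pmax(mu, region$start), region$end - 1))
  weights <- c(rep(0.8 / G, G), 0.2)
  if (mode == "pet") {
    list(G = G, mu = mu, weights = weights)
  } else {
    list(G = G, mu = mu, weights = weights, delta = delta0, sigma = sigma0,
         q = 0.5)
  }
}

# G highest coverage positions subject to a minimum mutual separation;
# falls back to midpoint quantiles for components beyond the available
# summits. Each summit is the centre of its tied coverage run.
.coverage_summits <- function(frag, region, G, min_sep) {
  W <- region$end - region$start
  diffarr <- numeric(W + 1L)
  a <- pmax(frag$left, region$start) - region$start + 1L
  b <- pmin(frag$right, region$end - 1L) - region$start + 1L
  ok <- a <= b
  idx <- c(a[ok], b[ok] + 1L)
  vals <- c(rep(1, sum(ok)), rep(-1, sum(ok)))
  agg <- rowsum(vals, idx)
  diffarr[as.integer(rownames(agg))] <- agg[, 1L]
  cov <- cumsum(diffarr[seq_len(W)])
  avail <- rep(TRUE, W)
  mu <- numeric(0)
  for (g in seq_len(G)) {
    if (!any(avail)) break
    cand <- which(avail)
    mx <- max(cov[cand])
    at_max <- cand[cov[cand] >= mx - 1e-12]
    runs <- rle(diff(c(-10L, at_max)) == 1L)
    # centre of the first maximal run of consecutive tied positions
    run_id <- cumsum(c(TRUE, diff(at_max) != 1L))
    lens <- tabulate(run_id)
    best_run <- which.max(lens)
    members <- at_max[run_id == best_run]
    pick <- members[ceiling(length(members) / 2)]
    mu <- c(mu, region$start + pick - 1L)
    avail[max(1L, pick - min_sep):min(W, pick + min_sep)] <- FALSE
  }
  if (length(mu) < G) {
    centers <- (frag$left + frag$right) / 2
    extra <- as.numeric(quantile(centers,
                                 probs = seq_len(G - length(mu)) / (G - length(mu) + 1),
                                 names = FALSE))
    mu <- c(mu, extra)
  }
  sort(mu)
}

# Weighted-coverage maximizer for the PET position update. The position
# update maximizes the observed log-likelihood profile in mu_g with all
# other parameters fixed: since the event emission is an indicator times
# 1/L, the profile is sum_i cover_i(mu) * w_i + const with per-fragment
# gains w_i = log1p(pi_g / (L_i * A_i)), A_i the mixture density excluding
# component g. The objective is piecewise constant in mu, so an exact pass
# over the 1-bp grid (via a difference array) finds the global maximum.
# Ties: centre of the longest run of tied positions.
.pet_mu_update <- function(left, right, r, region) {
  W <- region$end - region$start
  diffarr <- numeric(W + 1L)
  a <- pmax(left, region$start) - region$start + 1L
  b <- pmin(right, region$end - 1L) - region$start + 1L
  ok <- a <= b & r > 0
  if (!any(ok)) return(NA_real_)
  idx <- c(a[ok], b[ok] + 1L)
  vals <- c(r[ok], -r[ok])
  agg <- rowsum(vals, idx)
  diffarr[as.integer(rownames(agg))] <- agg[, 1L]
  cov <- cumsum(diffarr[seq_len(W)])
  mx <- max(cov)
  at_max <- abs(cov - mx) < 1e-12
  # longest run of tied maxima; first such run on further ties
  runs <- rle(at_max)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  centre_idx <- floor((starts[best] + ends[best]) / 2)
  region$start + centre_idx - 1L
}

.em_loglik_pet <- function(frag, region, mu, weights) {
  n <- nrow(frag)
  G <- length(mu)
  W <- region$end - region$start
  dens <- matrix(0, n, G + 1L)
  for (g in seq_len(G)) {
    dens[, g] <- ifelse(frag$left <= mu[g] & mu[g] <= frag$right,
                        1 / frag$length, 0)
  }
  dens[, G + 1L] <- 1 / W
  mixt <- dens %*% weights
  list(loglik = sum(log(mixt)), dens = dens, mixt = as.numeric(mixt))
}

# Coordinate-wise global maximization of the observed log-likelihood in
# each SET event position over the 1-bp grid, all other parameters fixed.
# Only moves that improve the log-likelihood are kept.
.set_mu_polish <- function(tags, region, mu, weights, delta, sigma, q) {
  G <- length(mu)
  W <- region$end - region$start
  grid <- seq.int(region$start, region$end - 1L)
  fwd <- tags$strand == "+"
  shifted <- tags$pos5 + ifelse(fwd, delta, -delta)
  coef <- ifelse(fwd, q, 1 - q)
  dens_grid <- dnorm(outer(shifted, grid, `-`), 0, sigma) * coef
  dens <- matrix(0, nrow(tags), G + 1L)
  for (g in seq_len(G)) {
    dens[, g] <- ifelse(fwd, q * dnorm(tags$pos5, mu[g] - delta, sigma),
                        (1 - q) * dnorm(tags$pos5, mu[g] + delta, sigma))
  }
  dens[, G + 1L] <- 0.5 / W
  for (g in seq_len(G)) {
    A <- as.numeric(dens[, -g, drop = FALSE] %*% weights[-g])
    ll_cur <- sum(log(A + weights[g] * dens[, g]))
    ll_grid <- colSums(log(A + weights[g] * dens_grid))
    best <- which.max(ll_grid)
    if (ll_grid[best] > ll_cur + 1e-9) {
      mu[g] <- grid[best]
      dens[, g] <- dens_grid[, best]
    }
  }
  mu
}

.em_loglik_set <- function(tags, region, mu, weights, delta, sigma, q) {
  n <- nrow(tags)
  G <- length(mu)
  W <- region$end - region$start
  fwd <- tags$strand == "+"
  dens <- matrix(0, n, G + 1L)
  for (g in seq_len(G)) {
    dens[, g] <- ifelse(fwd,
                        q * dnorm(tags$pos5, mu[g] - delta, sigma),
                        (1 - q) * dnorm(tags$pos5, mu[g] + delta, sigma))
  }
  dens[, G + 1L] <- 0.5 / W
  mixt <- dens %*% weights
  list(loglik = sum(log(mixt)), dens = dens, mixt = as.numeric(mixt))
}

#' Fit the binding-event mixture model by EM
#'
#' Alternates posterior assignment of each observation to the `G` event
#' components or background (E-step) with parameter updates (M-step) until
#' the relative log-likelihood change falls below `tol`. The PET position
#' update is an exact 1-bp grid maximization of responsibility-weighted
#' coverage; SET positions, the shared shift and spread have closed-form
#' weighted least-squares updates.
#'
#' @param obs Fragments (`mode = "pet"`) or tags (`mode = "set"`) assigned
#'   to the region.
#' @param region One-row region data.frame.
#' @param G Number of event components (>= 1).
#' @param mode `"pet"` or `"set"`.
#' @param init Optional parameter list, as from [init_params()].
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @param weight_floor Lower bound on mixture weights during EM (avoids
#'   `log(0)`; components may still collapse to this floor).
#' @param delta0,sigma0 Initialization for the SET nuisance parameters.
#' @param n_init Number of EM starts: the summit/quantile-based start plus
#'   `n_init - 1` jittered restarts; the fit with the best final
#'   log-likelihood is returned. The default single start suffices in
#'   practice because the position update is an exact profile-likelihood
#'   maximization.
#' @param seed Integer seed controlling the jittered restarts (results are
#'   deterministic given the seed).
#' @return A `"deconv_fit"` object: `params`, `loglik`, `bic`,
#'   `responsibilities` (n x (G+1)), `n_obs`, `converged`, `n_iter`,
#'   `degenerate` (all-background flag), `loglik_trace`.
#' @export
em_fit <- function(obs, region, G, mode = c("pet", "set"), init = NULL,
                   tol = 1e-6, max_iter = 500L, weight_floor = 1e-6,
                   delta0 = 100, sigma0 = 30, n_init = 1L, seed = 0L) {
  mode <- match.arg(mode)
  n <- nrow(obs)
  if (n < G + 1) stop("insufficient reads: ", n, " observations for G = ", G)
  if (is.null(init) && n_init > 1L) {
    base_init <- init_params(obs, region, G, mode,
                             delta0 = delta0, sigma0 = sigma0)
    W <- region$end - region$start
    best <- NULL
    for (k in seq_len(n_init)) {
      ini <- base_init
      if (k > 1L) {
        set.seed(seed + 1000L * k)
        ini$mu <- pmin(pmax(ini$mu + rnorm(G, 0, W / 10),
                            region$start), region$end - 1)
      }
      fit_k <- em_fit(obs, region, G, mode, init = ini, tol = tol,
                      max_iter = max_iter, weight_floor = weight_floor,
                      delta0 = delta0, sigma0 = sigma0, n_init = 1L)
      if (is.null(best) || fit_k$loglik > best$loglik) best <- fit_k
    }
    return(best)
  }
  if (is.null(init)) {
    init <- init_params(obs, region, G, mode, delta0 = delta0, sigma0 = sigma0)
  }
  mu <- init$mu
  weights <- init$weights
  delta <- init$delta
  sigma <- init$sigma
  q <- init$q
  W <- region$end - region$start
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  fwd <- if (mode == "set") obs$strand == "+" else NULL
  s_sign <- if (mode == "set") ifelse(fwd, 1, -1) else NULL

  polish_rounds <- 0L
  for (iter in seq_len(max_iter)) {
    ev <- if (mode == "pet") {
      .em_loglik_pet(obs, region, mu, weights)
    } else {
      .em_loglik_set(obs, region, mu, weights, delta, sigma, q)
    }
    ll <- ev$loglik
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      # SET positions: escape label-swap local optima with a coordinate-wise
      # global grid search of each mu_g given the others, then resume EM
      if (mode == "set" && polish_rounds < 3L) {
        polish_rounds <- polish_rounds + 1L
        new_mu <- .set_mu_polish(obs, region, mu, weights, delta, sigma, q)
        if (any(abs(new_mu - mu) > 0.5)) {
          mu <- new_mu
          ll_old <- ll
          next
        }
      }
      converged <- TRUE
      resp <- sweep(ev$dens, 2, weights, `*`) / ev$mixt
      break
    }
    ll_old <- ll
    # E-step
    resp <- sweep(ev$dens, 2, weights, `*`) / ev$mixt
    # M-step: weights
    weights <- colMeans(resp)
    weights <- pmax(weights, weight_floor)
    weights <- weights / sum(weights)
    # M-step: component parameters
    if (mode == "pet") {
      # exact coordinate ascent on the observed log-likelihood in each mu_g
      dens <- ev$dens
      for (g in seq_len(G)) {
        mixt_g <- as.numeric(dens %*% weights)
        A <- pmax(mixt_g - weights[g] * dens[, g], 1e-300)
        gain <- log1p(weights[g] / (obs$length * A))
        new_mu <- .pet_mu_update(obs$left, obs$right, gain, region)
        if (!is.na(new_mu)) {
          mu[g] <- new_mu
          dens[, g] <- ifelse(obs$left <= mu[g] & mu[g] <= obs$right,
                              1 / obs$length, 0)
        }
      }
    } else {
      wg <- colSums(resp[, seq_len(G), drop = FALSE])
      wg <- pmax(wg, 1e-12)
      # joint closed-form solution of the weighted least squares in
      # (mu_1..mu_G, delta): mu_g = m_g + delta * a_g and
      # delta = sum_g (w_g a_g m_g - b_g) / sum_g w_g (1 - a_g^2)
      m_g <- colSums(resp[, seq_len(G), drop = FALSE] * obs$pos5) / wg
      a_g <- colSums(resp[, seq_len(G), drop = FALSE] * s_sign) / wg
      b_g <- colSums(resp[, seq_len(G), drop = FALSE] * s_sign * obs$pos5)
      denom <- sum(wg * (1 - a_g^2))
      if (denom > 1e-9) {
        delta <- sum(wg * a_g * m_g - b_g) / denom
      }
      delta <- max(delta, 1)
      mu <- m_g + delta * a_g
      mu <- pmin(pmax(mu, region$start), region$end - 1)
      sse <- 0
      for (g in seq_len(G)) {
        sse <- sse + sum(resp[, g] * (obs$pos5 - (mu[g] - s_sign * delta))^2)
      }
      sigma <- max(sqrt(sse / sum(wg)), 1)
      q <- sum(resp[, seq_len(G), drop = FALSE][fwd, ]) / sum(wg)
      q <- min(max(q, 1e-6), 1 - 1e-6)
    }
  }
  if (!converged) {
    ev <- if (mode == "pet") {
      .em_loglik_pet(obs, region, mu, weights)
    } else {
      .em_loglik_set(obs, region, mu, weights, delta, sigma, q)
    }
    ll <- ev$loglik
    resp <- sweep(ev$dens, 2, weights, `*`) / ev$mixt
  }
  p_free <- if (mode == "pet") 2L * G else 2L * G + 3L
  params <- if (mode == "pet") {
    list(G = G, mu = mu, weights = weights, mode = "pet")
  } else {
    list(G = G, mu = mu, weights = weights, delta = delta, sigma = sigma,
         q = q, mode = "set")
  }
  degenerate <- sum(weights[seq_len(G)]) < 1e-3
  if (degenerate) {
    warning("all-background degenerate fit (event weight ",
            signif(sum(weights[seq_len(G)]), 3), ")")
  }
  structure(list(
    params = params,
    loglik = ll,
    bic = bic(ll, p_free, n),
    responsibilities = resp,
    n_obs = n,
    converged = converged,
    n_iter = length(loglik_trace),
    degenerate = degenerate,
    loglik_trace = loglik_trace
  ), class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  p <- x$params
  cat("binding-event mixture fit (", p$mode, "): G = ", p$G, "\n", sep = "")
  cat("  positions: ", paste(round(p$mu, 1), collapse = ", "), "\n", sep = "")
  cat("  weights:   ", paste(signif(p$weights, 3), collapse = ", "),
      " (last = background)\n", sep = "")
  if (p$mode == "set") {
    cat("  shift ", round(p$delta, 1), " bp, spread ", round(p$sigma, 1),
        " bp, P(forward) ", round(p$q, 3), "\n", sep = "")
  }
  cat("  loglik ", round(x$loglik, 2), ", BIC ", round(x$bic, 2), ", ",
      x$n_iter, " iterations, n = ", x$n_obs, "\n", sep = "")
  invisible(x)
}

#' Select the number of binding events by BIC
#'
#' Fits the mixture for `G = 1, ..., G_max` event components and returns the
#' minimum-BIC fit; exact ties go to the smaller model. Events in the
#' returned fit are sorted by position.
#'
#' @inheritParams em_fit
#' @param G_max Largest number of event components considered.
#' @param ... Passed to [em_fit()].
#' @return The selected `"deconv_fit"`, with `G_tried` and `bic_by_G`
#'   attached.
#' @export
select_model <- function(obs, region, mode = c("pet", "set"), G_max = 5L,
                         ...) {
  mode <- match.arg(mode)
  stopifnot(G_max >= 1)
  fits <- vector("list", G_max)
  errs <- character(G_max)
  for (G in seq_len(G_max)) {
    fits[[G]] <- tryCatch(
      suppressWarnings(em_fit(obs, region, G, mode, ...)),
      error = function(e) {
        errs[G] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) {
    stop("all fits failed: ",
         paste(sprintf("G=%d: %s", which(!ok), errs[!ok]), collapse = "; "))
  }
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic, 0)
  best_G <- which(bics <= min(bics) + 1e-12)[1]   # tie -> smaller G
  fit <- fits[[best_G]]
  ord <- order(fit$params$mu)
  fit$params$mu <- fit$params$mu[ord]
  fit$params$weights <- fit$params$weights[c(ord, fit$params$G + 1L)]
  fit$responsibilities <- fit$responsibilities[, c(ord, fit$params$G + 1L),
                                               drop = FALSE]
  attr(fit, "G_tried") <- which(ok)
  attr(fit, "bic_by_G") <- bics
  fit
}

#' Event table from a fitted region
#'
#' @param fit A `"deconv_fit"` from [select_model()] or [em_fit()].
#' @param region The fitted region (one row).
#' @return A `data.frame` with one row per event: `region_id`, `chrom`,
#'   `position` (0-based), `strength` (weight x reads), `weight`,
#'   `G_selected`, `bic`.
#' @export
events_from_fit <- function(fit, region) {
  p <- fit$params
  data.frame(
    region_id = region$region_id,
    chrom = region$chrom,
    position = as.integer(round(p$mu)),
    strength = p$weights[seq_len(p$G)] * fit$n_obs,
    weight = p$weights[seq_len(p$G)],
    G_selected = p$G,
    bic = fit$bic,
    stringsAsFactors = FALSE
  )
}
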