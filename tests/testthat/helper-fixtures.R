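# Shared fixtures and independent oracles, built in code at test time.

test_region <- function(start = 9000L, end = 11000L, chrom = "chrT",
                        id = "r1") {
  data.frame(chrom = chrom, start = start, end = end, region_id = id,
             stringsAsFactors = FALSE)
}

# a small deterministic fragment set
toy_fragments <- function() {
  df <- data.frame(chrom = "chrT",
                   left = c(100L, 110L, 120L),
                   right = c(150L, 160L, 170L))
  df$length <- df$right - df$left + 1L
  df
}

# SET tags drawn from the model's own generative process
sim_set_tags <- function(n, mu, delta = 75, sigma = 30, q = 0.5, seed = 1) {
  set.seed(seed)
  fwd <- runif(n) < q
  pos5 <- ifelse(fwd, rnorm(n, mu - delta, sigma), rnorm(n, mu + delta, sigma))
  data.frame(chrom = "chrT", pos5 = round(pos5),
             strand = ifelse(fwd, "+", "-"), stringsAsFactors = FALSE)
}

# Independent oracle: naive enumeration over all injective partial matchings
# (prediction -> truth), maximizing pairs then minimizing total distance.
brute_force_match <- function(predictions, truths, tolerance) {
  n <- length(predictions)
  m <- length(truths)
  best <- list(n = -1L, dist = Inf)
  recurse <- function(i, used, pairs, dist) {
    if (i > n) {
      cand_n <- if (is.null(pairs)) 0L else nrow(pairs)
      if (cand_n > best$n ||
          (cand_n == best$n && dist < best$dist - 1e-9)) {
        best <<- list(n = cand_n, dist = dist, pairs = pairs)
      }
      return(invisible())
    }
    recurse(i + 1L, used, pairs, dist)
    for (t in seq_len(m)) {
      if (t %in% used) next
      d <- abs(predictions[i] - truths[t])
      if (d < tolerance) {
        recurse(i + 1L, c(used, t),
                rbind(pairs, data.frame(pred = i, truth = t, distance = d)),
                dist + d)
      }
    }
  }
  recurse(1L, integer(0), NULL, 0)
  best
}

.fld_sd_test <- function(fld) {
  m <- sum(fld$support * fld$pmf)
  sqrt(sum(fld$support^2 * fld$pmf) - m^2)
}

# Independent oracle: fixed-weight exhaustive grid search of the PET/SET
# observed log-likelihood over all mu combinations on a 1-bp grid.
grid_search_loglik <- function(obs, region, weights, mode,
                               delta = NULL, sigma = NULL, q = NULL) {
  G <- length(weights) - 1L
  W <- region$end - region$start
  grid <- seq.int(region$start, region$end - 1L)
  one_comp_dens <- function(mu) {
    if (mode == "pet") {
      ifelse(obs$left <= mu & mu <= obs$right, 1 / obs$length, 0)
    } else {
      fwd <- obs$strand == "+"
      ifelse(fwd, q * dnorm(obs$pos5, mu - delta, sigma),
             (1 - q) * dnorm(obs$pos5, mu + delta, sigma))
    }
  }
  bg <- if (mode == "pet") 1 / W else 0.5 / W
  best <- -Inf
  if (G == 1L) {
    for (mu in grid) {
      ll <- sum(log(weights[1] * one_comp_dens(mu) + weights[2] * bg))
      if (ll > best) best <- ll
    }
  } else if (G == 2L) {
    dens_list <- lapply(grid, one_comp_dens)
    for (i in seq_along(grid)) {
      di <- dens_list[[i]]
      for (j in seq_along(grid)) {
        ll <- sum(log(weights[1] * di + weights[2] * dens_list[[j]] +
                        weights[3] * bg))
        if (ll > best) best <- ll
      }
    }
  } else {
    stop("grid oracle supports G <= 2")
  }
  best
}
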