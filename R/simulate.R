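# Generative simulator. Shares its covering convention with the PET
# emission: a fragment assigned to an event at mu has leftmost position
# uniform on {mu - L + 1, ..., mu}, so the fragment always covers mu.

#' Default fragment-length distribution for simulations
#'
#' A discretized Normal with mean 150 bp and standard deviation 20 bp,
#' truncated to \[50, 300\] bp — a stand-in for the empirical library-size
#' distribution of a sonicated ChIP library.
#'
#' @param mean,sd Normal parameters (bp).
#' @param min_len,max_len Truncation bounds (bp).
#' @return An `"fld"` object.
#' @export
default_length_dist <- function(mean = 150, sd = 20, min_len = 50L,
                                max_len = 300L) {
  support <- seq.int(min_len, max_len)
  pmf <- dnorm(support, mean, sd)
  fragment_length_dist(support, pmf)
}

#' Simulation specification
#'
#' @param region One-row regions `data.frame` (see [read_regions_bed()]);
#'   a plain list with `chrom`, `start`, `end`, `region_id` also works.
#' @param event_positions Event positions (bp, inside the region).
#' @param fragments_per_event Fragment count per event (recycled).
#' @param n_background Background fragment count; default 10% of the total
#'   event fragments.
#' @param length_dist An `"fld"`; default [default_length_dist()].
#' @return A `"sim_spec"` list.
#' @export
simulation_spec <- function(region, event_positions, fragments_per_event,
                            n_background = NULL, length_dist = NULL) {
  if (is.null(length_dist)) length_dist <- default_length_dist()
  fragments_per_event <- rep_len(fragments_per_event,
                                 length(event_positions))
  if (is.null(n_background)) {
    n_background <- round(0.1 * sum(fragments_per_event))
  }
  if (any(event_positions < region$start | event_positions >= region$end)) {
    stop("event positions must lie inside the region")
  }
  stopifnot(all(fragments_per_event >= 0), n_background >= 0)
  structure(list(region = region, event_positions = event_positions,
                 fragments_per_event = fragments_per_event,
                 n_background = n_background, length_dist = length_dist),
            class = "sim_spec")
}

#' Simulate PET fragments for a region with known events
#'
#' For each fragment assigned to event `g` at position `mu_g`: a length `L`
#' is drawn from the library-size distribution and the leftmost position
#' uniformly from the `L` start positions for which the fragment covers
#' `mu_g`; the rightmost position is `leftmost + L - 1`. Background
#' fragments get a uniform leftmost position within the region (they may
#' extend past its edge) and a length from the same distribution.
#'
#' @param spec A `"sim_spec"` from [simulation_spec()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list of class `"sim_dataset"` with `fragments` (including a
#'   `label` column: event index or `0` for background), `truth` (event
#'   positions) and `region`.
#' @export
simulate_pet <- function(spec, seed = 1L) {
  set.seed(seed)
  fld <- spec$length_dist
  max_L <- max(fld$support)
  if (any(spec$event_positions - max_L + 1 < 0)) {
    stop("event too close to coordinate 0 for the maximum fragment length")
  }
  pieces <- list()
  for (g in seq_along(spec$event_positions)) {
    n_g <- spec$fragments_per_event[g]
    if (n_g == 0) next
    mu <- spec$event_positions[g]
    L <- .sample_lengths(fld, n_g)
    left <- mu - L + 1L + floor(runif(n_g) * L)   # uniform on {mu-L+1..mu}
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = spec$region$chrom, left = as.integer(left),
      right = as.integer(left + L - 1L), length = as.integer(L),
      label = g, stringsAsFactors = FALSE)
  }
  if (spec$n_background > 0) {
    nb <- spec$n_background
    L <- .sample_lengths(fld, nb)
    left <- spec$region$start +
      floor(runif(nb) * (spec$region$end - spec$region$start))
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = spec$region$chrom, left = as.integer(left),
      right = as.integer(left + L - 1L), length = as.integer(L),
      label = 0L, stringsAsFactors = FALSE)
  }
  fragments <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(0), left = integer(0), right = integer(0),
               length = integer(0), label = integer(0))
  structure(list(fragments = fragments, tags = NULL,
                 truth = spec$event_positions, region = spec$region),
            class = "sim_dataset")
}

#' Derive SET tags from simulated PET fragments
#'
#' Emulates single-end sequencing of the same library: for each fragment one
#' of the two ends is sampled with equal probability — the left end as a
#' forward-strand tag or the right end as a reverse-strand tag. Component
#' labels carry over.
#'
#' @param dataset A `"sim_dataset"` with fragments.
#' @param seed Integer seed.
#' @return The dataset with a `tags` element filled in.
#' @export
derive_set <- function(dataset, seed = 1L) {
  set.seed(seed)
  fr <- dataset$fragments
  fwd <- runif(nrow(fr)) < 0.5
  dataset$tags <- data.frame(
    chrom = fr$chrom,
    pos5 = ifelse(fwd, fr$left, fr$right),
    strand = ifelse(fwd, "+", "-"),
    label = fr$label,
    stringsAsFactors = FALSE
  )
  dataset
}

#' Depth-matched quasi-SET construction
#'
#' For a fair PET-versus-SET comparison at matched read counts: every
#' fragment contributes one sampled end to the SET sample (2N fragments give
#' 2N single-end reads), while only a `keep_fraction` subset of fragments
#' (default one half, i.e. N fragments = 2N reads) is retained for the PET
#' sample.
#'
#' @param fragments Fragment `data.frame`.
#' @param keep_fraction Fraction of fragments kept for the PET subset.
#' @param seed Integer seed.
#' @return A list with `pet` (fragment subset) and `set` (tags).
#' @export
quasi_set_from_pet <- function(fragments, keep_fraction = 0.5, seed = 1L) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  set.seed(seed)
  n <- nrow(fragments)
  fwd <- runif(n) < 0.5
  tags <- data.frame(
    chrom = fragments$chrom,
    pos5 = ifelse(fwd, fragments$left, fragments$right),
    strand = ifelse(fwd, "+", "-"),
    stringsAsFactors = FALSE
  )
  if (!is.null(fragments$label)) tags$label <- fragments$label
  keep_n <- round(keep_fraction * n)
  keep <- if (keep_n >= n) seq_len(n) else sort(sample.int(n, keep_n))
  list(pet = fragments[keep, , drop = FALSE], set = tags)
}

#' Factorial simulation grid
#'
#' Generates a full factorial of datasets over inter-event distance and
#' per-event depth, each with `replicates` independent replicates. Every
#' dataset has two events placed symmetrically about the region centre at
#' the requested distance. Seeds are derived reproducibly from the base
#' seed and the cell index.
#'
#' @param distances Inter-event distances (bp).
#' @param depths Fragments per event.
#' @param replicates Replicates per cell.
#' @param region Region to simulate in.
#' @param n_background Background fragments per dataset (default 10% of
#'   event fragments).
#' @param length_dist `"fld"` used for all cells.
#' @param seed Base seed.
#' @return A `data.frame` with columns `distance`, `depth`, `replicate`,
#'   `seed` and a list-column `dataset` of `"sim_dataset"` objects.
#' @export
simulate_grid <- function(distances, depths, replicates, region,
                          n_background = NULL, length_dist = NULL,
                          seed = 1L) {
  stopifnot(length(distances) >= 1, length(depths) >= 1, replicates >= 1)
  cells <- expand.grid(replicate = seq_len(replicates), depth = depths,
                       distance = distances)
  cells <- cells[, c("distance", "depth", "replicate")]
  centre <- floor((region$start + region$end) / 2)
  cells$seed <- (seed * 10007L + seq_len(nrow(cells)) * 131L) %% .Machine$integer.max
  cells$dataset <- lapply(seq_len(nrow(cells)), function(i) {
    d <- cells$distance[i]
    mu <- c(centre - floor(d / 2), centre - floor(d / 2) + d)
    spec <- simulation_spec(region, mu, cells$depth[i],
                            n_background = n_background,
                            length_dist = length_dist)
    simulate_pet(spec, seed = cells$seed[i])
  })
  cells
}
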