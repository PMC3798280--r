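# chipdeconv

High-resolution deconvolution of protein binding events inside ChIP-Seq
peaks, for paired-end (PET) and single-end (SET) libraries.

## Who this is for

Peak callers report one interval — often hundreds of base pairs wide — and
one summit per peak. In compact genomes (the motivating case is the
*E. coli* sigma-70 / RNA-polymerase system) promoters sit only tens of
base pairs apart, so a single "peak" routinely hides several distinct
binding events, and condition-specific promoter switching is invisible at
peak level. `chipdeconv` takes candidate peak regions plus the aligned
reads inside them and estimates the number and base-pair positions of the
individual binding events in each region.

## The model in brief

Each candidate region of width W is a finite mixture of G binding-event
components and one uniform background with weights
π₁,…,π_G, π₀:

* **PET** — a fragment `[l, r]` of length `L` from the event at μ_g covers
  it, with leftmost position uniform over the L covering starts:
  `p(l | L, g) = (1/L)·1{l ≤ μ_g ≤ r}`; lengths follow the empirical
  library-size distribution; background fragments are uniform over the
  region (density 1/W).
* **SET** — the 5' end x of a forward read is `N(μ_g − δ, σ²)`, of a
  reverse read `N(μ_g + δ, σ²)`, with strand ~ Bernoulli(q); the shift δ,
  spread σ and q are shared within a region and re-estimated per region;
  background is uniform × fair strand coin.

Fitting is by EM (with exact 1-bp grid position updates for PET and a
closed-form joint (μ, δ) least-squares step for SET) and the number of
events is chosen by BIC, `−2ℓ + p·log n`, with p = 2G (PET) or 2G+3
(SET), ties to the smaller model.

Companion modules: a generative read simulator (PET, derived SET and
depth-matched quasi-SET), exact-enumeration + Monte-Carlo probabilities of
*invasion* and *truncation* (the two ways a fixed read-extension length
corrupts single-end information between close events), a windowed
conditional-binomial candidate-region caller with Benjamini–Hochberg
control, and an evaluation suite (optimal event matching, sensitivity,
resolution, differential occupancy across conditions).

## Worked example

Two binding events 150 bp apart, 300 fragments each, 10% background:

```r
library(chipdeconv)

region <- data.frame(chrom = "chrSim", start = 9000L, end = 11000L,
                     region_id = "peak_1")
spec <- simulation_spec(region, event_positions = c(9900, 10050),
                        fragments_per_event = 300, n_background = 30)
ds  <- simulate_pet(spec, seed = 7)
fit <- select_model(ds$fragments, region, mode = "pet", G_max = 5)
fit
#> binding-event mixture fit (pet): G = 2
#>   positions: 9900, 10050
#>   weights:   0.474, 0.476, 0.0502 (last = background)
#>   loglik -3718.47, BIC 7462.72, 5 iterations, n = 630

events_from_fit(fit, region)
#>   region_id  chrom position strength    weight G_selected      bic
#> 1    peak_1 chrSim     9900 298.6852 0.4741035          2 7462.716
#> 2    peak_1 chrSim    10050 299.7195 0.4757453          2 7462.716
```

BIC selected G = 2 out of five candidate models; both positions are
recovered exactly; the strength column (weight × region reads, here ≈ 300
fragments each) ranks events for downstream filtering. `write_events()`
exports this table 1-based with a companion BED; `run_deconvolution()`
loops it over a whole regions file.

A shell front end wraps the same functions:

```sh
Rscript inst/scripts/chipdeconv.R deconvolve \
    --reads frags.bedpe --regions peaks.bed --mode pet --out events.tsv
```

with sibling subcommands `regions`, `simulate`, `invasion`, `evaluate`.

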