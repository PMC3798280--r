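---
title: "Deconvolving closely spaced binding events in ChIP-Seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving closely spaced binding events in ChIP-Seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdeconv)
```

## The problem

Prokaryotic transcription factors and the housekeeping sigma factor bind
promoters at sites that are frequently separated by only tens of base
pairs. Standard ChIP-Seq peak callers report one interval of hundreds of
base pairs per peak and at most one "summit", so multiple adjacent binding
events collapse into a single call. `chipdeconv` addresses the downstream
problem: given a candidate peak region and the aligned reads inside it,
estimate *how many* binding events the region contains and *where* each
one sits, for both paired-end (PET) and single-end (SET) libraries.

## The model

Each candidate region of width $W$ is modelled as a mixture of $G$
binding-event components and one background component with proportions
$\pi_1,\dots,\pi_G,\pi_0$.

**PET.** A sequenced fragment is an interval $[l, r]$ of length
$L = r - l + 1$. A fragment generated by an event at position $\mu_g$ must
cover it, and conditional on $L$ its leftmost position is uniform over the
$L$ start positions that achieve coverage:
$$ p(l \mid L, g) = \frac{1}{L}\,\mathbf{1}\{l \le \mu_g \le r\}. $$
Fragment lengths follow the empirical library-size distribution, which is
shared by all components and therefore cancels from the mixture.
Background fragments have uniform leftmost position over the region,
density $1/W$.

**SET.** Only one 5' end $x$ and the strand are observed. Conditional on
the strand the 5' end is Normal with a region-specific shift $\delta$
(about half the library size) and spread $\sigma$:
forward reads $x \sim N(\mu_g - \delta, \sigma^2)$, reverse reads
$x \sim N(\mu_g + \delta, \sigma^2)$; the strand itself is Bernoulli with
forward probability $q$ shared by the event components. $\delta$, $\sigma$
and $q$ are common to all events in a region but re-estimated per region,
which accommodates the region-to-region heterogeneity of effective library
sizes. Background reads are uniform over the region with a fair strand
coin, density $(1/W)\cdot(1/2)$.

Parameters are estimated by expectation-maximization and the number of
events $G \in \{1, \dots, G_{\max}\}$ (default $G_{\max}=5$) is selected by
the Bayesian information criterion
$\mathrm{BIC} = -2\ell + p\,\log n$, with $p = 2G$ free parameters for PET
($G$ positions, $G$ free weights) and $p = 2G + 3$ for SET (adding
$\delta$, $\sigma$, $q$). Ties go to the smaller model.

## Estimation: what is standard and what is not

The E-step and the weight updates are textbook EM. The position updates
deserve comment.

**PET positions.** Because the event emission is an indicator times $1/L$,
the observed log-likelihood as a function of one position $\mu_g$ (all
other parameters held fixed) is an additive, piecewise-constant coverage
sum: each fragment contributes $\log(1 + \pi_g / (L_i A_i))$ on the
interval it covers, where $A_i$ is the mixture density of observation $i$
excluding component $g$. We maximize this profile exactly on the 1-bp grid
with a difference array (ties resolved to the centre of the longest tied
run). We deliberately use the *observed-likelihood* profile rather than
the EM Q-function here: under the hard coverage indicator, fragments that
do not cover the current $\mu_g$ have exactly zero responsibility, so a
Q-function (responsibility-weighted) position update can never move
$\mu_g$ outside the intersection of its currently covering fragments. In
experiments with two events 150 bp apart that Q-style update trapped
two-component fits between the events in a substantial fraction of
datasets and the BIC then compensated with spurious extra components.
Exact coordinate ascent on the observed likelihood has no such trap, keeps
the log-likelihood monotone by construction, and selected the true
$G = 2$ in 100/100 simulated datasets under the default study conditions.

**SET positions.** $\mu_1,\dots,\mu_G$ and the shared shift $\delta$ have
a closed-form joint weighted-least-squares M-step; $\sigma^2$ and $q$
follow by weighted moments. Because a Normal mixture over positions can
have label-swap local optima when components are narrow, a converged fit
is polished by a coordinate-wise *global* 1-bp grid search of each
$\mu_g$ given the others (at most three rounds, only accepted when the
log-likelihood improves), after which EM resumes. This keeps the final fit
at least as good as any fixed-nuisance grid solution in our tests.

**Initialization.** PET components start at the $G$ highest mutually
separated summits of the raw fragment-coverage profile (minimum separation
100 bp), with midpoint quantiles as a fallback and an optional
`strategy = "quantile"`. SET components start at evenly spaced quantiles of
strand-corrected 5' ends with $\delta_0 = 100$ bp and $\sigma_0 = 30$ bp.
`n_init` jittered restarts are available but the default single start
suffices because the position updates are exact.

**Numerical safeguards.** Mixture weights are floored at $10^{-6}$ during
EM (components may collapse to the floor and are still reported);
$\delta$ and $\sigma$ are floored at 1 bp; convergence is declared at a
relative log-likelihood change below $10^{-6}$ or 500 iterations. A fit
whose total event weight falls below $10^{-3}$ is flagged degenerate
(all-background) and returned with a warning. Fragments lying wholly
outside the region keep a finite likelihood through the background
component rather than being dropped.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `G_max` | 5 | largest number of event components tried per region |
| `tolerance` | 20 bp | identification distance for evaluation/matching |
| `delta0`, `sigma0` | 100, 30 bp | SET initial shift and spread |
| `min_len`, `max_len` | 50, 500 bp | window for the empirical length pmf |
| `window`, `gap`, `alpha` | 50 bp, 100 bp, 0.05 | region caller settings |
| `flank` | max fragment length | read-to-region assignment extension |

The 20-bp identification tolerance is deliberately stringent — prokaryotic
promoters sit tens of base pairs apart, so a looser criterion would count
merged predictions as successes. It is a required, visible parameter of
every evaluation function rather than a hidden constant.

Reads are assigned to a region when their 5' end (SET) falls inside, or
their fragment (PET) overlaps, the region extended by `flank` on both
sides; fragments informative for an event at a region boundary can start
outside the region, and the maximum library size bounds how far away such
a fragment can lie.

## The simulator and what it does (not) emulate

`simulate_pet()` implements the generative process of the PET model
itself: per event fragment, a length from the library-size distribution
and a leftmost position uniform over the covering set (the same constant
defines the emission, so simulator and model cannot drift apart);
background fragments start uniformly in the region and may protrude past
its edges. `derive_set()` emulates single-end sequencing by keeping one
random end per fragment, and `quasi_set_from_pet()` builds depth-matched
PET/SET pairs (all ends for SET, half the fragments for PET) for fair
head-to-head comparisons. The default length distribution is a discretized
Normal (mean 150 bp, sd 20 bp, truncated to [50, 300] bp), a stated
stand-in for a sonicated library; `estimate_length_distribution()`
replaces it with the empirical pmf whenever PET data are available.
Background defaults to 10% of the event fragments.

The simulator draws reads i.i.d. given the truth. It does not emulate PCR
duplicates, mappability gaps, GC bias, sequence-dependent fragmentation or
inter-replicate biological variability — so passing tests demonstrate
correctness of the estimation machinery under the stated model, not
robustness to every artefact of real libraries. The model's goodness of
fit to real ChIP-Seq data has to be judged on real data.

## Invasion and truncation

For SET analysis the unknown fragment extent must be replaced by a fixed
extension length $\hat L$. Two failure modes arise for a fragment
generated by the first of two events $d$ bp apart: *invasion* (the true
fragment covers only its own event, but the extended read covers both —
over-extension) and *truncation* (the true fragment covers both events,
but the extended read covers exactly one — under-extension). Both
probabilities are computed two ways: an exhaustive enumeration over the
discrete (length, leftmost, sequenced-end) space, which is exact under the
generative model and serves as the reference, and Monte-Carlo sampling
with binomial standard errors. The spread multiplier `sd_scale` rescales
lengths about the distribution mean and re-truncates at 1 bp, so curves
can be drawn as a function of library-size variability. Both probabilities
concentrate at short inter-event distances; invasion is non-monotone in
$d$ because at very short distances most true fragments already cover both
events, so there is little left to invade.

## Candidate regions

A lightweight caller tiles the observed read span into non-overlapping
windows (default 50 bp), tests each non-empty window — conditional
binomial against the ChIP depth fraction with a control, Poisson against
the genome-wide mean rate without — applies Benjamini-Hochberg across the
tested windows, and merges significant windows closer than `gap`.
Zero-count windows are excluded from the multiple-testing family because
they carry no evidence and only inflate the correction. This caller is a
convenience: any external peak caller's BED output can be supplied via
`read_regions_bed()` and is the expected route for production analyses.

## Design choices made where the design was open

* **Free-parameter counts for BIC** (2G and 2G+3) count exactly the
  estimated quantities; the mixture weight simplex contributes $G$ free
  parameters.
* **Strand probability**: background strand is fixed at 1/2 (non-specific
  binding has no strand preference); event components share one estimated
  $q$.
* **One $\sigma$ for both strands**: the strand-conditional Normals share
  a single spread; nothing in our exploratory fits suggested the reverse
  strand needs its own.
* **No post-hoc merging** of nearly coincident events: BIC is the sole
  complexity control, and collapsed components are reported with their
  (near-floor) weights.
* **Event strength** is reported as weight × region read count — a
  read-count scale on which predictions can be ranked and thresholded.
* **Matching** for evaluation is an optimal one-to-one assignment
  (maximize matches, then minimize total distance, ties by lexicographic
  pair order) rather than greedy matching, so one prediction can never be
  credited with two truths. Sensitivity for regions with more than two
  true events requires *all* truths matched.
* **Assignment flank**: how reads spanning region borders are attached to
  regions is not dictated by the model; the flank-extension rule above is
  this package's choice and is configurable.

## Problem sizes used by the test-suite and acceptance script

Simulated studies use one 2-kb region, events 50 or 150 bp apart, 300
fragments per event and 10% background, with 100 seeds per claim (30 for
the depth-scaling check); the invasion/truncation grid uses 20 (distance,
spread) cells at 20,000 Monte-Carlo draws each; the null-calibration study
uses 200 replicates of 800 reads over 10 kb. These sizes give binomial
standard errors of a few percent on every reported rate while keeping a
full run in the low minutes on one core.

## Known limitations

* The PET emission treats fragment length as ancillary; length-dependent
  immunoprecipitation efficiency is not modelled.
* SET fits inherit the usual fragility of Normal mixtures at very low
  read counts; the grid polish mitigates but cannot remove it.
* BIC with $n = $ region read count is a heuristic for weakly identified
  mixtures; very deep regions with heavy non-specific binding may still
  warrant an extra component.
* The candidate-region caller ignores mappability and GC covariates by
  design; use a full peak caller when those matter.
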