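---
title: "Simulating IBD segments around a focal locus: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating IBD segments around a focal locus: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdlocus)
```

## The model

Consider `n` diploid individuals, hence `2n` sampled haplotypes, and one
focal position on a chromosome. Backward in time the haplotype lineages
coalesce; forward along the chromosome each meiosis places crossovers as a
Poisson process of rate 1 per Morgan. For a branch of length `dt`
generations, the distance from the focal point to the nearest crossover on a
given side is therefore `Exponential(dt)` (in Morgans). The IBD segment
shared by haplotypes `a` and `b` extends, on each side, to the minimum
crossover distance over all branches on the genealogical path from `a` to
`b`; the pair is *detectable* if left + right extent reaches a threshold `w`.

The simulator maintains, per uncoalesced lineage, a set of *haplotype
records*: groups of sample ids together with their current left/right
endpoint distances. Extending a lineage along its branch draws one left and
one right exponential distance shared by all its records, and each record
keeps the componentwise minimum. At a coalescence every record pair across
the two joining lineages is compared (shared endpoints are again
componentwise minima) and every sample cross pair whose shared length reaches
`w` is emitted exactly once, with the event time as its TMRCA; then the
records pool into the merged lineage.

Endpoints can only shrink. Two exact consequences are the package's core
optimizations:

* **Pruning** removes a record once `left + right < w`: it can never again
  contribute a detectable segment.
* **Merging** collapses two records of one lineage whose `(left, right)`
  pairs are *exactly* equal (floating-point equality is intentional: equality
  arises only by both records inheriting the same shared branch minima, never
  by coincidence of independent continuous draws). The collapsed record
  carries the union of the sample sets; after the collapse both original
  record groups report identical shared endpoints in all later comparisons,
  which is also why merged pairs are reported with common endpoint values.

The probability that two records come to share an endpoint grows quickly with
time above their common ancestor: after coalescing at time `u`, a further
branch of length `v` shares its draw with probability `v / (2u + v)`
(`merge_probability()`), which tends to 1 for the long branches near the
root — exactly where the number of record comparisons would otherwise
explode (`expected_comparisons()` gives the `n (n-1) 4^{-j}` expectation at
bifurcation depth `j`).

## Genealogy engine

The coalescent engine is a hybrid:

* **Discrete Wright–Fisher phase.** While `(k / N(t))^3 >= 1e-3` (with `k`
  the current lineage count and `N(t)` the haploid size; the threshold is
  configurable via `engine_config()`), time advances one generation at a
  time. The number of coalescing pairs is drawn as
  `Binomial(choose(k, 2), 1 / N')` with `N'` the parental-generation size,
  capped at `floor(k / 2)` (a message reports when the cap binds), and the
  `2m` participating lineages are drawn uniformly without replacement and
  paired: every simultaneous event is a pairwise merger. This captures the
  many simultaneous mergers that the Kingman limit forbids but that occur
  when samples are large relative to `N`.
* **Continuous Kingman phase.** Once the statistic falls below the
  threshold the engine switches — one-way, evaluated each generation — to
  exponential waiting times with the cumulative rate
  `integral of choose(k,2) / N(u) du` inverted in closed form per
  piecewise-exponential epoch (`coalescent_wait_time()`).

Population sizes are **haploid** and demographies are piecewise exponential
in backward time: epochs `[start, end)` with `N(t) = size * exp(rate * (t -
start))`, the last epoch extending to infinity with rate exactly 0 so the
rate integral always diverges. Negative backward rates encode forward-time
growth; `forward_growth_demography()` performs the conversion. Three
scenarios ship in `build_scenario()`: `"constant"`, `"bottleneck"` (growth
with an instantaneous 100-fold crash 20 generations ago) and
`"three_phase_growth"` (accelerating growth over the last 300 generations).
The scenario parameter values are this package's defaults, chosen to exercise
growth, a discontinuity, and multi-epoch chaining; they are not calibrated to
any particular population.

## Selective sweeps

A hard sweep with selection coefficient `s` and present-day carrier frequency
`p0` is modelled by the structured coalescent. Backward in time the carrier
frequency follows the logistic decay

`p(t) = p0 / (p0 + (1 - p0) exp(s t))`,

and lineages are split into carrier and non-carrier groups coalescing within
subpopulations of haploid sizes `N(t) p(t)` and `N(t) (1 - p(t))`. The same
hybrid rule applies per group. The structured phase ends at the *de novo
time*, when the carrier subpopulation falls below a floor — by default 1.5
haploid copies (`floor_rule = "haploid_floor"`); `p(t) < 1/N` is available as
an alternative — at which point all lineages pool into one panmictic group.
Carrier status of the samples is user-supplied (`carriers`/`carrier_count`)
or drawn binomially at `p0`; binomial draws reflect that a random sample
contains a random number of carriers.

Design choices here, made as package decisions: the logistic trajectory is
the default because it is the deterministic limit used for closed-form work,
while a discrete per-generation recursion (`trajectory = "discrete"`) is kept
for comparison — the two differ by at most about `0.11 * s` over a sweep
(the per-generation `O(s^2)` gap accumulates over the `~1/s` generations of
the sweep), which the test suite asserts. The 1.5-haploid floor avoids the
degenerate tail where a size below ~1 makes rates infinite while still ending
the structured phase close to where a single ancestral copy remains.

## Numerical choices

* **Two RNG streams.** Tree events and recombination draws come from two
  independent streams derived from one seed. Optimizations change *how many*
  recombination draws would be consumed in a naive implementation, so a
  single stream would desynchronize variants; with separate streams, and with
  `retain_empty = TRUE` so empty lineages still occupy tree events, all four
  variants (`optimized`, `prune_only`, `merge_only`, `naive`) of one seed
  yield the *identical* segment set. This is the package's strongest
  correctness check (`test-acceptance.R`, 50 replicates at 1,000 haplotypes).
  By default the optimized variant does drop record-empty lineages — exact in
  distribution by the sampling consistency of the coalescent, and verified
  distributionally in the test suite.
* **Sweep-phase waiting times are numeric.** Within a subpopulation the rate
  `choose(k,2) / (N(t) p(t))` has no convenient closed-form integral, so
  waiting times accumulate the rate generation by generation at the midpoint
  of each unit step (resolution well under a tenth of a generation, checked
  against the closed form where one exists). Outside the sweep the closed-
  form epoch inversion is used.
* **Deferred redraws.** When a scheduled Kingman event crosses an epoch or
  regime boundary it is discarded and redrawn from the boundary —
  valid by the memorylessness of the exponential.
* **Degenerate sizes.** If the pooled population size drops below 2 haploids
  while lineages remain, remaining lineages are coalesced at one-generation
  spacing with a one-time warning.
* **Exact float equality for merging** (see above) and componentwise `pmin`
  comparisons, chunked so no expanded grid exceeds ~4e6 elements, keep memory
  bounded at large `n`.
* **Chromosome ends.** Endpoints may start at finite bounds
  (`chrom_bounds`), modelling a locus at a given distance from the two
  chromosome ends; otherwise segments are unbounded, appropriate when `w` is
  small relative to the chromosome.

## What the generator does and does not emulate

Output is the exact set of detectable pairwise IBD segments *at one locus*
under the neutral or swept coalescent with Poisson recombination (no
interference, no gene conversion), a single panmictic population (apart from
the sweep structure), and non-overlapping generations. It does not produce
genome-wide segment sets, sequence variation, or genotyping/phasing error;
detection is a sharp length threshold `w`, not a probabilistic detector.
TMRCAs are reported per pair at their true common ancestor, so the output is
suitable as ground truth for IBD-based inference of recent `N(t)` or sweeps.

## Validation and problem sizes

The test suite validates, among others: the waiting-time inversion against
numeric quadrature on random demographies; pair TMRCA laws (exponential via
Kolmogorov–Smirnov, geometric via an exact probability-integral transform);
conditional segment length `Gamma(2, 2t)` at fixed TMRCA (10^4 draws);
detectable fractions against the closed-form tails; endpoint-sharing
frequencies against `v/(2u+v)` on a `(u, v)` grid; the comparison-count
recursion at `n = 1024`; exact optimized-vs-naive equality at 400 and 1,000
haplotypes (50 seeds), neutral and swept; monotonicity of mean segment counts
in `s` (200 replicates at 1,000 haplotypes); and a scaling smoke test at
16,000 haplotypes asserting the naive variant is strictly slowest (absolute
runtimes are hardware-bound and deliberately not asserted; at that size the
pruning-only, merging-only and combined variants are within a small factor of
one another). These sizes are the package's own test choices, balancing
statistical power against a few minutes of total runtime.

## Limitations

* Single focal locus per run; correlations between loci are out of scope.
* Hard sweeps only, with a deterministic trajectory: no stochastic
  frequency paths, standing variation, or recurrent mutation.
* One panmictic population; no migration or admixture.
* The discrete WF phase uses the binomial pairwise approximation (triple
  mergers are split into pairs within a generation), the standard
  regime-matched approximation; its event-count mean `k(k-1)/(2N')` and the
  hybrid's expected event times are verified in the tests.

```{r example}
d <- build_scenario("bottleneck")
segs <- simulate_ibd(d, n_individuals = 100, w = 0.01, seed = 1)
glance(segs)
```
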