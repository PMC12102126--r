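# Closed-form coalescent and recombination quantities used for validation and
# study design. Conventions: N is haploid; times are generations unless a
# function says otherwise; segment lengths and thresholds are Morgans.

#' Haldane map function
#'
#' Converts genetic distance to recombination frequency under the no-
#' interference Poisson crossover model: `rho = 0.5 (1 - exp(-2 d))`.
#'
#' @param d Genetic distance in Morgans (`>= 0`, vectorized).
#' @return Recombination frequency in `[0, 0.5)`.
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  0.5 * (1 - exp(-2 * d))
}

#' Tail probability of a detectable haplotype segment
#'
#' Conditional on a coalescent time of `Nt` generations, the single-haplotype
#' segment length to the right of the focal point is `Exponential(Nt)` and
#' the width overlapping it is `Gamma(2, Nt)`, giving upper-tail
#' probabilities `exp(-Nt w)` and `exp(-Nt w) (1 + Nt w)` at threshold `w`.
#' For the segment *shared* by two haplotypes with TMRCA `t` generations,
#' substitute `Nt = 2 t` (two meiotic paths).
#'
#' @param w Detection threshold, Morgans (`> 0`).
#' @param Nt Coalescent time in generations (`> 0`).
#' @param which `"width"` (overlapping segment, default) or `"right"`
#'   (one-sided).
#' @return Probability.
#' @export
detectable_tail <- function(w, Nt, which = c("width", "right")) {
  which <- match.arg(which)
  stopifnot(all(w > 0), all(Nt > 0))
  if (which == "right") exp(-Nt * w) else exp(-Nt * w) * (1 + Nt * w)
}

#' Expected time until the coalescent reaches k lineages
#'
#' Starting from `n` sampled haploids in a constant haploid population of size
#' `N`, the expected total time (generations) until `n - k + 1` coalescent
#' events have occurred, i.e. until `k - 1` lineages remain:
#' `N * 2 * (1/(k-1) - 1/n)`. `n = Inf` drops the `1/n` term.
#'
#' @param n Sample size (haploids); may be `Inf`.
#' @param k Target lineage count (`2 <= k <= n`).
#' @param N Constant haploid population size.
#' @return Expected time in generations.
#' @examples
#' expected_plus_time(Inf, 40, 10000)   # 512.82
#' expected_plus_time(Inf, 400, 100000) # 501.25
#' @export
expected_plus_time <- function(n, k, N) {
  if (any(k < 2)) stop("k must be >= 2", call. = FALSE)
  if (any(k > n)) stop("k must be <= n", call. = FALSE)
  N * 2 * (1 / (k - 1) - 1 / n)
}

#' Probability that two haplotypes share a recombination endpoint
#'
#' Haplotypes that coalesced at time `u` share the endpoint drawn on the
#' branch from their ancestor over the following `v` generations with
#' probability `v / (2 u + v)` (per side: the shared branch draw must be the
#' minimum of the three competing exponentials).
#'
#' @param u Time from the samples to their common ancestor, generations.
#' @param v Further branch length above that ancestor, generations.
#' @return Probability `v / (2 u + v)`.
#' @export
merge_probability <- function(u, v) {
  stopifnot(all(u > 0), all(v > 0))
  v / (2 * u + v)
}

#' Asymptotic merge probability between coalescent stages
#'
#' Probability that the shared endpoint above the `(n-k)`-th coalescent event
#' dominates by the `(n-j)`-th, with `u/2 = 1/k - 1/n` and
#' `v/2 = 1/j - 1/k` (expected coalescent times): equal to
#' `(1/j - 1/k) / (1/j + 1/k - 2/n)`, which tends to 1 when `j = o(k)`.
#'
#' @param n Sample size (may be `Inf`).
#' @param k,j Lineage-count stages with `j < k <= n`.
#' @return Probability.
#' @export
stage_merge_probability <- function(n, k, j) {
  if (any(j >= k)) stop("requires j < k", call. = FALSE)
  if (any(k > n)) stop("requires k <= n", call. = FALSE)
  (1 / j - 1 / k) / (1 / j + 1 / k - 2 / n)
}

#' Expected number of endpoint comparisons near the root
#'
#' Under recursive random bifurcation of an `n`-leaf tree
#' (`B_j ~ Binomial(B_{j-1}, 1/2)`, `B_0 = n`), the expected number of
#' cross-subtree comparisons at stage `j` is `n (n - 1) 4^{-j}` — the same
#' order as the worst case `n^2 / 4^j`, which is why most comparison work
#' without pruning/merging happens at the oldest coalescent events.
#'
#' @param n Number of leaves (`>= 2`).
#' @param j Bifurcation depth (`>= 1`).
#' @return Expected comparison count.
#' @export
expected_comparisons <- function(n, j) {
  stopifnot(all(n >= 2), all(j >= 1))
  n * (n - 1) * 2^(-2 * j)
}

#' Expected pairwise coalescences in one Wright-Fisher generation
#'
#' Mean of the `Binomial(choose(k, 2), 1/N')` approximation:
#' `k (k - 1) / (2 N')`.
#'
#' @param k Lineage count (`>= 2`).
#' @param N_prime Haploid population size of the parental generation.
#' @return Expected number of coalescing pairs.
#' @export
wf_event_mean <- function(k, N_prime) {
  stopifnot(all(k >= 2))
  k * (k - 1) / (2 * N_prime)
}
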