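# Hard selective sweep: deterministic backward allele-frequency trajectory for
# genic selection. Backward in time, the frequency p(t) of the beneficial
# allele decays from its present-day value p0; the carrier and non-carrier
# subpopulations have allele-specific haploid sizes N(t) p(t) and
# N(t) (1 - p(t)). Once the carrier subpopulation is too small to hold two
# distinct ancestors, the sweep has reached its de novo mutation time and the
# structured coalescent collapses to a single panmictic population.

#' Define a hard selective sweep
#'
#' @param s Selection coefficient (`s >= 0`); the per-generation advantage of
#'   the sweeping allele under genic selection. `s = 0` gives a constant
#'   trajectory (and no de novo time; request neutral simulation instead).
#' @param p0 Present-day frequency of the sweeping allele, in (0, 1).
#' @param floor_rule How the de novo mutation time is detected:
#'   `"haploid_floor"` (default) declares it when the carrier subpopulation
#'   `N(t) p(t)` drops below `floor_haploids`; `"inverse_N"` uses
#'   `p(t) < 1 / N(t)`.
#' @param floor_haploids Carrier-size floor for `"haploid_floor"`
#'   (default 1.5: below this a lineage can no longer meet a distinct carrier
#'   ancestor).
#' @param trajectory `"logistic"` (default) uses the continuous logistic
#'   solution of genic selection; `"discrete"` iterates the per-generation
#'   selection recursion backward.
#' @return An object of class `sweep_model`.
#' @examples
#' sw <- sweep_model(s = 0.04, p0 = 0.5)
#' frequency_at(sw, c(0, 50, 100))
#' @export
sweep_model <- function(s, p0,
                        floor_rule = c("haploid_floor", "inverse_N"),
                        floor_haploids = 1.5,
                        trajectory = c("logistic", "discrete")) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0,
            is.numeric(p0), length(p0) == 1L, p0 > 0, p0 < 1,
            floor_haploids > 0)
  structure(
    list(s = s, p0 = p0,
         floor_rule = match.arg(floor_rule),
         floor_haploids = floor_haploids,
         trajectory = match.arg(trajectory)),
    class = "sweep_model"
  )
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(sprintf("Hard sweep: s = %g, p0 = %g (%s trajectory, %s floor)\n",
              x$s, x$p0, x$trajectory, x$floor_rule))
  invisible(x)
}

#' Allele frequency backward in time
#'
#' For a positive selection coefficient the frequency decays backward in time
#' following the logistic solution of genic selection,
#' `p(t) = p0 / (p0 + (1 - p0) exp(s t))`. The `"discrete"` trajectory instead
#' inverts the per-generation selection map
#' `p -> p (1 + s) / (1 + s p)` one generation at a time; the two agree to
#' `O(s^2)` per generation.
#'
#' @param model A [sweep_model()].
#' @param t Generations before present (vectorized, `t >= 0`).
#' @return Frequency `p(t)` in (0, 1].
#' @export
frequency_at <- function(model, t) {
  stopifnot(inherits(model, "sweep_model"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  s <- model$s; p0 <- model$p0
  if (s == 0) return(rep(p0, length(t)))
  if (model$trajectory == "logistic") {
    p0 / (p0 + (1 - p0) * exp(s * t))
  } else {
    vapply(t, function(tt) .discrete_backward_freq(p0, s, tt), numeric(1))
  }
}

# invert the forward genic-selection map for floor(t) whole generations, then
# interpolate the fractional remainder on the logistic curve anchored there
.discrete_backward_freq <- function(p0, s, t) {
  g <- floor(t)
  p <- p0
  if (g > 0) for (i in seq_len(g)) p <- p / ((1 + s) - s * p)
  frac <- t - g
  if (frac > 0) p <- p / (p + (1 - p) * exp(s * frac))
  p
}

#' Allele-specific subpopulation sizes
#'
#' The carrier and non-carrier subpopulations have haploid effective sizes
#' `N(t) p(t)` and `N(t) (1 - p(t))`; they always sum to `N(t)`.
#'
#' @param model A [sweep_model()].
#' @param demog A [demography()].
#' @param t Generations before present (vectorized).
#' @return A tibble with columns `t`, `carrier`, `non_carrier`.
#' @export
subpopulation_sizes <- function(model, demog, t) {
  N <- size_at(demog, t)
  p <- frequency_at(model, t)
  tibble::tibble(t = t, carrier = N * p, non_carrier = N * (1 - p))
}

#' Time of the sweeping allele's de novo mutation
#'
#' The first backward time at which the carrier subpopulation can no longer
#' contain two distinct ancestral lineages; after this time the two
#' subpopulations merge into one panmictic population. Under the default rule
#' this is the first `t` with `N(t) p(t) < floor_haploids`; under
#' `"inverse_N"` it is the first `t` with `p(t) < 1 / N(t)`.
#'
#' @param model A [sweep_model()] with `s > 0`.
#' @param demog A [demography()].
#' @return Time in generations.
#' @examples
#' denovo_time(sweep_model(0.04, 0.5), build_scenario("constant"))
#' @export
denovo_time <- function(model, demog) {
  stopifnot(inherits(model, "sweep_model"), inherits(demog, "demography"))
  if (model$s == 0) {
    stop("s = 0: the trajectory never reaches the frequency floor; ",
         "use neutral simulation instead", call. = FALSE)
  }
  crit <- function(t) {
    # positive while the carrier subpopulation is still viable
    if (model$floor_rule == "haploid_floor") {
      size_at(demog, t) * frequency_at(model, t) - model$floor_haploids
    } else {
      frequency_at(model, t) - 1 / size_at(demog, t)
    }
  }
  if (crit(0) <= 0) return(0)
  # bracket: step forward in doubling windows until the criterion goes negative
  hi <- 16
  while (crit(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e9) stop("de novo time not reached within 1e9 generations",
                       call. = FALSE)
  }
  # first crossing: scan unit generations from the present (N(t) p(t) need not
  # be monotone under a varying demography), then bisect within the generation
  grid <- seq(0, ceiling(hi))
  vals <- vapply(grid, crit, numeric(1))
  first_neg <- which(vals <= 0)[1L]
  a <- grid[first_neg - 1L]
  b <- grid[first_neg]
  uniroot(crit, c(a, b), tol = 1e-10)$root
}
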