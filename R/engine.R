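# Hybrid discrete Wright-Fisher / Kingman coalescent engine.
#
# While the number of uncoalesced lineages k is large relative to the
# population size (k^3 / N(t)^3 >= switch_threshold), the engine advances
# generation by generation, drawing the number of simultaneous pairwise
# coalescences from Binomial(choose(k,2), 1/N') and pairing 2m lineages
# uniformly at random (all simultaneous events are pairwise; no triple
# mergers). Once the statistic falls below the threshold the engine switches
# permanently to continuous time, drawing inter-event waits by inverting the
# cumulative pairwise coalescence rate under N(t).
#
# With a hard sweep the process runs independently inside the carrier and
# non-carrier subpopulations (sizes N(t) p(t) and N(t) (1 - p(t))) until the
# de novo mutation time, after which the remaining lineages are pooled.

#' Engine configuration
#'
#' @param switch_threshold Switch from discrete Wright-Fisher to continuous
#'   Kingman time once `k^3 / N(t)^3` falls below this value (default `1e-3`);
#'   the switch is evaluated at each generation and is one-way.
#' @param force_wf Never leave the discrete Wright-Fisher phase.
#' @param force_kingman Start (and stay) in continuous Kingman time.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(switch_threshold = 1e-3,
                          force_wf = FALSE,
                          force_kingman = FALSE) {
  stopifnot(switch_threshold > 0, switch_threshold <= 1,
            !(force_wf && force_kingman))
  structure(list(switch_threshold = switch_threshold,
                 force_wf = force_wf, force_kingman = force_kingman),
            class = "engine_config")
}

#' Discrete-to-continuous switch statistic
#'
#' `k^3 / N^3`, the quantity controlling the accuracy of the binomial
#' approximation of per-generation coalescence counts: the approximation is
#' accurate when it is small. For `k = 2e4` lineages in a population of
#' `N = 2e5` haploids it equals `1e-3`.
#'
#' @param k Lineage count.
#' @param N Haploid population size.
#' @return `(k / N)^3`.
#' @export
switch_statistic <- function(k, N) (k / N)^3

#' One Wright-Fisher generation of pairwise coalescences
#'
#' Draws the number of coalescing pairs `m ~ Binomial(choose(k, 2), 1/N')`,
#' capped at `floor(k/2)`, then selects `2m` distinct lineages uniformly at
#' random and pairs them. Every simultaneous event is a pairwise merger.
#'
#' @param k Number of lineages entering the generation (`k >= 2`).
#' @param N_prime Haploid population size of the parental generation
#'   (`N_prime >= 2`).
#' @return A list with `m` (number of coalescing pairs) and `pairs` (an
#'   `m x 2` integer matrix of lineage indices in `1:k`). Uses the session
#'   RNG.
#' @examples
#' set.seed(1)
#' wf_generation_events(1000, 5000)$m
#' @export
wf_generation_events <- function(k, N_prime) {
  stopifnot(k >= 2, N_prime >= 2)
  n_pairs <- k * (k - 1) / 2
  m <- rbinom(1L, size = n_pairs, prob = min(1, 1 / N_prime))
  cap <- floor(k / 2)
  if (m > cap) {
    message("binomial coalescence count capped at floor(k/2) = ", cap)
    m <- cap
  }
  if (m == 0L) return(list(m = 0L, pairs = matrix(integer(0), ncol = 2)))
  chosen <- sample.int(k, 2L * m, replace = FALSE)
  list(m = as.integer(m), pairs = matrix(chosen, ncol = 2L, byrow = TRUE))
}

# numeric inversion of the cumulative coalescence rate for an arbitrary size
# function (used for sweep subpopulations, where N(t) p(t) has no closed-form
# integral): per-generation midpoint accumulation, linear within a step
.wait_time_numeric <- function(size_fun, k, t0, e, t_max = Inf) {
  ck2 <- k * (k - 1) / 2
  t <- t0
  acc <- 0
  repeat {
    step_end <- floor(t) + 1
    if (step_end <= t) step_end <- t + 1
    if (step_end > t_max) step_end <- t_max
    if (step_end <= t) return(Inf)
    rate <- ck2 / size_fun((t + step_end) / 2)
    inc <- rate * (step_end - t)
    if (acc + inc >= e) return(t + (e - acc) / rate)
    acc <- acc + inc
    t <- step_end
    if (t >= t_max) return(Inf)
  }
}

# ---------------------------------------------------------------------------
# engine object: a mutable environment delivering one coalescent event at a
# time, so the IBD consumer can interleave (dropping pruned-empty lineages and
# stopping early)

.engine_new <- function(demog, n_haploids, sweep = NULL, carriers = NULL,
                        config = engine_config(), tree_stream) {
  stopifnot(inherits(demog, "demography"), n_haploids >= 2)
  eng <- new.env(parent = emptyenv())
  eng$demog <- demog
  eng$cfg <- config
  eng$stream <- tree_stream
  eng$t <- 0
  eng$next_id <- as.integer(n_haploids) + 1L
  eng$queue <- list()
  eng$q_head <- 1L
  eng$warned_degenerate <- FALSE
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_model"))
    eng$t_dn <- denovo_time(sweep, demog)
    car <- sort(unique(as.integer(carriers)))
    non <- setdiff(seq_len(n_haploids), car)
    eng$groups <- list(
      .group_new("carrier", car,
                 function(t) size_at(demog, t) * frequency_at(sweep, t),
                 closed_form = FALSE, cfg = config, t0 = 0),
      .group_new("non_carrier", non,
                 function(t) size_at(demog, t) * (1 - frequency_at(sweep, t)),
                 closed_form = FALSE, cfg = config, t0 = 0)
    )
    eng$merged <- FALSE
  } else {
    eng$t_dn <- 0
    eng$groups <- list(
      .group_new("merged", seq_len(n_haploids), function(t) size_at(demog, t),
                 closed_form = TRUE, cfg = config, t0 = 0)
    )
    eng$merged <- TRUE
  }
  eng
}

.group_new <- function(label, ids, size_fun, closed_form, cfg, t0) {
  g <- new.env(parent = emptyenv())
  g$label <- label
  g$ids <- as.integer(ids)
  g$size_fun <- size_fun
  g$closed_form <- closed_form
  g$mode <- "wf"
  g$pending <- NULL       # list(time, i, j) for a scheduled Kingman event
  .group_update_mode(g, cfg, t0)
  g
}

.group_update_mode <- function(g, cfg, t) {
  if (g$mode == "kingman") return(invisible())
  if (cfg$force_wf) return(invisible())
  k <- length(g$ids)
  if (cfg$force_kingman ||
      (k >= 2 && switch_statistic(k, g$size_fun(t)) < cfg$switch_threshold)) {
    g$mode <- "kingman"
    g$pending <- NULL
  }
  invisible()
}

# schedule the group's next continuous-time event from global time t
.group_schedule <- function(eng, g, t) {
  k <- length(g$ids)
  if (k < 2) { g$pending <- NULL; return(invisible()) }
  t_max <- if (eng$merged) Inf else eng$t_dn
  ev_t <- with_stream(eng$stream, {
    e <- rexp(1)
    tt <- if (g$closed_form) {
      .wait_time_scalar(eng$demog, k, t, e)
    } else {
      .wait_time_numeric(g$size_fun, k, t, e, t_max)
    }
    if (tt > t_max) tt <- Inf
    if (is.finite(tt)) {
      pr <- sample.int(k, 2L)
      list(time = tt, i = pr[1L], j = pr[2L])
    } else {
      NULL
    }
  })
  g$pending <- ev_t
  invisible()
}

# apply one coalescence inside group g between member positions i, j at time t;
# returns the event record
.group_coalesce <- function(eng, g, i, j, t) {
  c1 <- g$ids[i]; c2 <- g$ids[j]
  parent <- eng$next_id
  eng$next_id <- eng$next_id + 1L
  g$ids <- c(g$ids[-c(i, j)], parent)
  g$pending <- NULL
  list(time = t, child1 = min(c1, c2), child2 = max(c1, c2),
       parent = parent, subpop = g$label)
}

# one Wright-Fisher generation for group g ending at integer-valued time t
.group_wf_generation <- function(eng, g, t) {
  k <- length(g$ids)
  if (k < 2) return(invisible())
  Np <- g$size_fun(t)
  if (Np < 2) {
    # degenerate: fewer than two parents available; all lineages must pair up
    if (g$label == "merged" && !eng$warned_degenerate) {
      warning("population size < 2 with >= 2 lineages; forcing coalescences",
              call. = FALSE)
      eng$warned_degenerate <- TRUE
    }
    m <- floor(k / 2)
    chosen <- with_stream(eng$stream, sample.int(k, 2L * m))
    pairs <- matrix(chosen, ncol = 2L, byrow = TRUE)
  } else {
    res <- with_stream(eng$stream, wf_generation_events(k, Np))
    if (res$m == 0L) return(invisible())
    pairs <- res$pairs
  }
  # queue the generation's events; positions refer to g$ids *before* removal,
  # so resolve ids now and rewrite membership in one batch
  kids <- g$ids[as.vector(t(pairs))]
  n_ev <- nrow(pairs)
  parents <- seq.int(eng$next_id, length.out = n_ev)
  eng$next_id <- eng$next_id + n_ev
  for (r in seq_len(n_ev)) {
    c1 <- kids[2L * r - 1L]; c2 <- kids[2L * r]
    eng$queue[[length(eng$queue) + 1L]] <-
      list(time = t, child1 = min(c1, c2), child2 = max(c1, c2),
           parent = as.integer(parents[r]), subpop = g$label)
  }
  g$ids <- c(g$ids[-as.vector(pairs)], as.integer(parents))
  invisible()
}

# pool subpopulations at the de novo time
.engine_merge_groups <- function(eng) {
  ids <- unlist(lapply(eng$groups, function(g) g$ids))
  demog <- eng$demog
  g <- .group_new("merged", ids, function(t) size_at(demog, t),
                  closed_form = TRUE, cfg = eng$cfg, t0 = eng$t_dn)
  eng$groups <- list(g)
  eng$merged <- TRUE
  eng$t <- max(eng$t, eng$t_dn)
  invisible()
}

.engine_total_k <- function(eng) {
  sum(vapply(eng$groups, function(g) length(g$ids), integer(1)))
}

# deliver the next coalescent event, or NULL when only one lineage remains
.engine_next <- function(eng) {
  repeat {
    if (eng$q_head <= length(eng$queue)) {
      ev <- eng$queue[[eng$q_head]]
      eng$q_head <- eng$q_head + 1L
      if (eng$q_head > length(eng$queue)) {
        eng$queue <- list()
        eng$q_head <- 1L
      }
      return(ev)
    }
    if (.engine_total_k(eng) <= 1L) return(NULL)
    if (!eng$merged &&
        all(vapply(eng$groups, function(g) length(g$ids) < 2, logical(1)))) {
      # no within-group events possible before the de novo time
      .engine_merge_groups(eng)
      next
    }
    # candidate continuous-time events
    for (g in eng$groups) {
      if (g$mode == "kingman" && is.null(g$pending) && length(g$ids) >= 2) {
        .group_schedule(eng, g, max(eng$t, 0))
      }
    }
    pend_times <- vapply(eng$groups, function(g) {
      if (g$mode == "kingman" && !is.null(g$pending)) g$pending$time else Inf
    }, numeric(1))
    any_wf <- any(vapply(eng$groups, function(g) {
      g$mode == "wf" && length(g$ids) >= 2
    }, logical(1)))
    next_gen <- if (any_wf) floor(eng$t) + 1 else Inf
    t_next <- min(c(pend_times, next_gen))
    if (!eng$merged && t_next >= eng$t_dn) {
      .engine_merge_groups(eng)
      next
    }
    if (is.infinite(t_next)) {
      # remaining groups idle (e.g. Kingman event deferred past the de novo
      # time in an unmerged engine); pooling handled above, so this means done
      return(NULL)
    }
    if (t_next < next_gen) {
      gi <- which.min(pend_times)
      g <- eng$groups[[gi]]
      ev <- .group_coalesce(eng, g, g$pending$i, g$pending$j, t_next)
      eng$t <- t_next
      .group_update_mode(g, eng$cfg, t_next)
      return(ev)
    }
    # advance one Wright-Fisher generation
    eng$t <- next_gen
    for (g in eng$groups) {
      if (g$mode == "wf" && length(g$ids) >= 2) {
        .group_wf_generation(eng, g, next_gen)
        .group_update_mode(g, eng$cfg, next_gen)
      }
    }
  }
}

# consumer dropped lineages (record lists emptied); remove from the active set
.engine_remove <- function(eng, ids) {
  for (g in eng$groups) {
    hit <- g$ids %in% ids
    if (any(hit)) {
      g$ids <- g$ids[!hit]
      g$pending <- NULL  # k changed; reschedule (exponential waits memoryless)
    }
  }
  invisible()
}

#' Simulate the coalescent event sequence
#'
#' Generates the ordered sequence of pairwise coalescent events for
#' `n_haploids` sample lineages under a demography, using the hybrid discrete
#' Wright-Fisher / continuous Kingman scheme, optionally structured into
#' carrier and non-carrier subpopulations for a hard sweep. Lineage ids
#' `1:n_haploids` are the samples; internal nodes are numbered upward from
#' `n_haploids + 1`.
#'
#' @param demog A [demography()].
#' @param n_haploids Number of sampled haploids (`>= 2`).
#' @param sweep Optional [sweep_model()].
#' @param carriers Integer ids of sampled haploids carrying the sweeping
#'   allele (required with `sweep`).
#' @param config An [engine_config()].
#' @param seed Integer seed for the tree randomness (optional if
#'   `tree_stream` given).
#' @param tree_stream Optionally, an [rng_stream()] to draw from instead of
#'   creating one from `seed`.
#' @param until_k Stop once this many lineages remain (default 1: run to the
#'   root).
#' @return A tibble with columns `time` (generations), `child1`, `child2`,
#'   `parent` (lineage ids) and `subpop` (`"carrier"`, `"non_carrier"` or
#'   `"merged"`), in non-decreasing time order, ending when `until_k`
#'   lineages remain.
#' @examples
#' d <- build_scenario("constant", N_haploid = 5000)
#' simulate_coalescent(d, n_haploids = 6, seed = 1)
#' @export
simulate_coalescent <- function(demog, n_haploids, sweep = NULL,
                                carriers = NULL, config = engine_config(),
                                seed = NULL, tree_stream = NULL,
                                until_k = 1L) {
  if (is.null(tree_stream)) {
    if (is.null(seed)) stop("supply seed or tree_stream", call. = FALSE)
    tree_stream <- rng_stream(seed)
  }
  eng <- .engine_new(demog, n_haploids, sweep, carriers, config, tree_stream)
  n_max <- n_haploids - 1L
  times <- numeric(n_max); c1 <- integer(n_max); c2 <- integer(n_max)
  par <- integer(n_max); sp <- character(n_max)
  i <- 0L
  i_stop <- n_haploids - as.integer(until_k)
  repeat {
    if (i >= i_stop) break
    ev <- .engine_next(eng)
    if (is.null(ev)) break
    i <- i + 1L
    times[i] <- ev$time; c1[i] <- ev$child1; c2[i] <- ev$child2
    par[i] <- ev$parent; sp[i] <- ev$subpop
  }
  keep <- seq_len(i)
  tibble::tibble(time = times[keep], child1 = c1[keep], child2 = c2[keep],
                 parent = par[keep], subpop = sp[keep])
}
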