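# IBD segment core.
#
# Each uncoalesced lineage carries haplotype records. A record is a set of
# sample haplotype ids together with the current left and right recombination
# endpoint distances (Morgans) from the focal point. When a lineage is
# extended along a branch of length dt generations, ONE left and ONE right
# crossover distance ~ Exponential(dt) are drawn and shared by all its
# records; each record keeps the componentwise minimum. Endpoints therefore
# only shrink, which makes two optimizations exact:
#   * pruning  - a record whose left + right falls below the detection
#                threshold w can never again produce a detectable segment;
#   * merging  - two records of one lineage with exactly equal (left, right)
#                behave identically in every future comparison and are
#                collapsed into one record with the union of their samples
#                (equality arises only by both inheriting the shared branch
#                minima, never by numeric coincidence).
# At a coalescence, every record pair across the two joining lineages is
# compared: shared endpoints are the componentwise minima, and each sample
# cross pair with shared length >= w yields one IBD segment with the event
# time as its TMRCA.

# records are a list: l (numeric), r (numeric), s (list of integer id vectors)
.recs_new <- function(samples, left, right) {
  list(l = as.numeric(left), r = as.numeric(right),
       s = lapply(samples, as.integer))
}

.recs_count <- function(recs) length(recs$l)

# shared branch draws applied to all records; optional pruning
.apply_branch <- function(recs, draw_left, draw_right, w, prune) {
  if (length(recs$l) == 0L) return(recs)
  l <- pmin(recs$l, draw_left)
  r <- pmin(recs$r, draw_right)
  if (prune) {
    keep <- (l + r) >= w
    if (!all(keep)) {
      return(list(l = l[keep], r = r[keep], s = recs$s[keep]))
    }
  }
  list(l = l, r = r, s = recs$s)
}

# collapse records with exactly equal (left, right); union their sample sets;
# deterministic order by smallest contained sample id
.merge_records <- function(recs) {
  n <- length(recs$l)
  if (n < 2L) return(recs)
  # equal (l, r) requires equal l; cheap exit when all left endpoints differ
  if (!anyDuplicated(recs$l)) {
    ord <- order(vapply(recs$s, min, numeric(1)))
    return(list(l = recs$l[ord], r = recs$r[ord], s = recs$s[ord]))
  }
  key <- paste(sprintf("%.17g", recs$l), sprintf("%.17g", recs$r))
  first <- match(key, key)
  if (!anyDuplicated(first)) {
    uniq <- first
  } else {
    uniq <- unique(first)
    recs <- list(
      l = recs$l[uniq],
      r = recs$r[uniq],
      s = lapply(uniq, function(u) unlist(recs$s[first == u], use.names = FALSE))
    )
  }
  ord <- order(vapply(recs$s, min, numeric(1)))
  list(l = recs$l[ord], r = recs$r[ord], s = recs$s[ord])
}

# compare all record pairs across two lineages; returns segment columns.
# chunked so the expanded grids never exceed ~4e6 elements
.compare_records <- function(rx, ry, w, t, chunk = 4e6) {
  nx <- length(rx$l); ny <- length(ry$l)
  empty <- list(sample_a = integer(0), sample_b = integer(0),
                left = numeric(0), right = numeric(0), tmrca = numeric(0))
  if (nx == 0L || ny == 0L) return(empty)
  block <- max(1L, floor(chunk / ny))
  out_a <- list(); out_b <- list(); out_l <- list(); out_r <- list()
  oi <- 0L
  start <- 1L
  iy_base <- rep.int(seq_len(ny), 1L)
  while (start <= nx) {
    end <- min(nx, start + block - 1L)
    ixs <- seq.int(start, end)
    ix <- rep(ixs, each = ny)
    iy <- rep.int(seq_len(ny), length(ixs))
    sl <- pmin(rx$l[ix], ry$l[iy])
    sr <- pmin(rx$r[ix], ry$r[iy])
    ok <- which((sl + sr) >= w)
    if (length(ok) > 0L) {
      sa <- rx$s[ix[ok]]
      sb <- ry$s[iy[ok]]
      la <- lengths(sa); lb <- lengths(sb)
      a <- unlist(mapply(function(u, v) rep(u, each = length(v)), sa, sb,
                         SIMPLIFY = FALSE), use.names = FALSE)
      b <- unlist(mapply(function(u, v) rep.int(v, length(u)), sa, sb,
                         SIMPLIFY = FALSE), use.names = FALSE)
      oi <- oi + 1L
      out_a[[oi]] <- a
      out_b[[oi]] <- b
      out_l[[oi]] <- rep.int(sl[ok], la * lb)
      out_r[[oi]] <- rep.int(sr[ok], la * lb)
    }
    start <- end + 1L
  }
  if (oi == 0L) return(empty)
  a <- unlist(out_a, use.names = FALSE)
  b <- unlist(out_b, use.names = FALSE)
  l <- unlist(out_l, use.names = FALSE)
  r <- unlist(out_r, use.names = FALSE)
  swap <- a > b
  if (any(swap)) {
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  list(sample_a = a, sample_b = b, left = l, right = r,
       tmrca = rep.int(t, length(a)))
}

#' Create a lineage state
#'
#' A lineage is an uncoalesced ancestral line carrying haplotype records: sets
#' of sample haplotype ids sharing current left/right endpoint distances (in
#' Morgans) from the focal point.
#'
#' @param samples A list of integer vectors (one sample set per record) or a
#'   single integer vector (one singleton record per sample).
#' @param left,right Endpoint distances per record, Morgans (default `Inf`;
#'   finite values model chromosome ends).
#' @param node_time Time of the lineage's most recent node, generations
#'   (0 for sample lineages).
#' @param id Lineage id.
#' @return An object of class `lineage_state`.
#' @export
lineage_state <- function(samples, left = Inf, right = Inf,
                          node_time = 0, id = 1L) {
  if (!is.list(samples)) samples <- lapply(samples, identity)
  n <- length(samples)
  left <- rep_len(left, n); right <- rep_len(right, n)
  stopifnot(all(left > 0), all(right > 0), n >= 0)
  structure(list(id = as.integer(id), node_time = node_time,
                 recs = .recs_new(samples, left, right)),
            class = "lineage_state")
}

#' Extend a lineage along its branch to a later time
#'
#' Draws one left and one right crossover distance `~ Exponential(t -
#' node_time)` (rates per Morgan, branch length in generations), shared by all
#' the lineage's records; each record keeps the componentwise minimum of its
#' endpoints and the draws. With `prune = TRUE`, records whose total possible
#' length falls below `w` are removed — exact for detectable output because
#' endpoints only shrink.
#'
#' @param lineage A [lineage_state()].
#' @param t Target time in generations (`> node_time`).
#' @param w Detection threshold, Morgans.
#' @param stream Optional [rng_stream()] for the crossover draws (session RNG
#'   if `NULL`).
#' @param prune Remove undetectable records (default `TRUE`).
#' @return The updated [lineage_state()].
#' @export
extend_branch <- function(lineage, t, w, stream = NULL, prune = TRUE) {
  stopifnot(inherits(lineage, "lineage_state"))
  dt <- t - lineage$node_time
  if (dt <= 0) stop("t must exceed the lineage's node_time", call. = FALSE)
  draws <- if (is.null(stream)) rexp(2L, rate = dt) else {
    with_stream(stream, rexp(2L, rate = dt))
  }
  lineage$recs <- .apply_branch(lineage$recs, draws[1L], draws[2L], w, prune)
  lineage$node_time <- t
  lineage
}

#' Coalesce two lineages and report detectable IBD segments
#'
#' Extends both lineages to the event time `t`, compares every record pair
#' across the two lineages (shared endpoints are the componentwise minima),
#' emits one IBD segment per sample cross pair whose shared length reaches
#' `w`, then pools the records into the merged lineage, collapsing records
#' with exactly equal endpoints when `merge = TRUE`.
#'
#' @param x,y Distinct [lineage_state()] objects.
#' @param t Event time, generations (`> max(node times)`).
#' @param w Detection threshold, Morgans.
#' @param stream Optional [rng_stream()] for the crossover draws.
#' @param merge Collapse equal-endpoint records (default `TRUE`).
#' @param prune Remove undetectable records (default `TRUE`).
#' @param id Id for the merged lineage (default `x$id`).
#' @return A list with `lineage` (the merged [lineage_state()]) and
#'   `segments` (a tibble with `sample_a`, `sample_b`, `left`, `right`,
#'   `tmrca`).
#' @export
coalesce_and_report <- function(x, y, t, w, stream = NULL,
                                merge = TRUE, prune = TRUE, id = x$id) {
  stopifnot(inherits(x, "lineage_state"), inherits(y, "lineage_state"),
            x$id != y$id)
  x <- extend_branch(x, t, w, stream, prune)
  y <- extend_branch(y, t, w, stream, prune)
  segs <- .compare_records(x$recs, y$recs, w, t)
  pooled <- list(l = c(x$recs$l, y$recs$l),
                 r = c(x$recs$r, y$recs$r),
                 s = c(x$recs$s, y$recs$s))
  if (merge) pooled <- .merge_records(pooled)
  merged <- structure(list(id = as.integer(id), node_time = t, recs = pooled),
                      class = "lineage_state")
  list(lineage = merged,
       segments = tibble::as_tibble(segs[c("sample_a", "sample_b",
                                           "left", "right", "tmrca")]))
}

#' Simulate detectable IBD segments around a focal locus
#'
#' Runs the full simulation: `2 * n_individuals` sample haplotypes start at
#' time 0 with records extending to infinity (or to finite chromosome bounds),
#' the hybrid coalescent engine generates pair coalescences under the
#' demography (optionally structured by a hard sweep), and every coalescence
#' compares and pools haplotype records, emitting each detectable pairwise
#' segment once, at the pair's most recent common ancestor.
#'
#' Variants map to the four implementation strategies: `"optimized"`
#' (pruning and merging), `"prune_only"`, `"merge_only"`, and `"naive"`
#' (neither; every record retained and the tree run to its root). With the
#' same seed all variants produce exactly the same segment set; `"naive"`
#' serves as the correctness oracle for the optimizations.
#'
#' @param demog A [demography()].
#' @param n_individuals Number of diploid individuals (`2 *n_individuals`
#'   haploids are simulated).
#' @param w Detection threshold in Morgans (`> 0`).
#' @param sweep Optional [sweep_model()].
#' @param seed Integer seed; two independent streams (tree events,
#'   recombination draws) are derived from it.
#' @param variant `"optimized"` (default), `"prune_only"`, `"merge_only"` or
#'   `"naive"`.
#' @param chrom_bounds Optional length-2 numeric `c(left, right)` in Morgans:
#'   initial endpoint distances modelling finite chromosome ends (default
#'   infinite).
#' @param retain_empty Keep record-empty lineages in the coalescent process
#'   (default `FALSE`: they are dropped, which is distributionally exact by
#'   sampling consistency; set `TRUE` when an identical tree across variants
#'   is needed, as in the exactness oracle).
#' @param carriers With `sweep`: integer ids of carrier haplotypes. If `NULL`,
#'   `carrier_count` haplotypes are sampled, or carrier status is drawn
#'   binomially at the present-day frequency `p0`.
#' @param carrier_count With `sweep`: fix the number of carrier haplotypes.
#' @param config An [engine_config()].
#' @param events Optionally, a precomputed event tibble from
#'   [simulate_coalescent()] to replay instead of running the engine live.
#' @return A tibble of class `ibd_sim` with columns `sample_a`, `sample_b`,
#'   `left_morgans`, `right_morgans`, `length_morgans`, `tmrca_generations`,
#'   `group_a`, `group_b`, ordered by TMRCA then sample ids. Attributes
#'   record `n_individuals`, `w`, `seed`, `variant` and carrier ids.
#' @examples
#' d <- build_scenario("constant", N_haploid = 5000)
#' segs <- simulate_ibd(d, n_individuals = 50, w = 0.01, seed = 1)
#' glance(segs)
#' @export
simulate_ibd <- function(demog, n_individuals, w, sweep = NULL, seed = NULL,
                         variant = c("optimized", "prune_only",
                                     "merge_only", "naive"),
                         chrom_bounds = NULL, retain_empty = FALSE,
                         carriers = NULL, carrier_count = NULL,
                         config = engine_config(), events = NULL) {
  stopifnot(inherits(demog, "demography"),
            n_individuals >= 1, is.numeric(w), length(w) == 1L, w > 0)
  variant <- match.arg(variant)
  if (is.null(seed)) seed <- sample.int(1e6, 1L)
  prune <- variant %in% c("optimized", "prune_only")
  merge <- variant %in% c("optimized", "merge_only")
  if (variant == "naive") retain_empty <- TRUE
  early_stop <- variant != "naive"
  n_hap <- 2L * as.integer(n_individuals)

  if (!is.null(chrom_bounds)) {
    stopifnot(length(chrom_bounds) == 2L, all(chrom_bounds > 0))
    left0 <- chrom_bounds[1L]; right0 <- chrom_bounds[2L]
  } else {
    left0 <- Inf; right0 <- Inf
  }

  streams <- .derive_streams(seed)

  groups <- rep("none", n_hap)
  if (!is.null(sweep)) {
    if (is.null(carriers)) {
      carriers <- with_stream(streams$tree, {
        if (!is.null(carrier_count)) {
          sample.int(n_hap, carrier_count)
        } else {
          which(runif(n_hap) < sweep$p0)
        }
      })
    }
    carriers <- sort(unique(as.integer(carriers)))
    groups[carriers] <- "carrier"
    groups[setdiff(seq_len(n_hap), carriers)] <- "non_carrier"
  }

  # event source: live engine or replay cursor
  live <- is.null(events)
  if (live) {
    eng <- .engine_new(demog, n_hap, sweep, carriers, config, streams$tree)
  } else {
    ev_i <- 0L
    n_ev <- nrow(events)
  }
  next_event <- function() {
    if (live) return(.engine_next(eng))
    if (ev_i >= n_ev) return(NULL)
    ev_i <<- ev_i + 1L
    as.list(events[ev_i, ])
  }
  drop_empty <- live && prune && !retain_empty

  # lineage storage (max id = 2 * n_hap - 1)
  recs <- vector("list", 2L * n_hap)
  node_time <- numeric(2L * n_hap)
  init_alive <- if (prune) (left0 + right0) >= w else TRUE
  for (i in seq_len(n_hap)) {
    recs[[i]] <- if (init_alive) .recs_new(list(i), left0, right0) else
      .recs_new(list(), numeric(0), numeric(0))
  }
  total_recs <- if (init_alive) n_hap else 0L

  seg_chunks <- list()
  sc <- 0L

  if (!(early_stop && total_recs <= 1L)) {
    repeat {
      ev <- next_event()
      if (is.null(ev)) break
      x <- ev$child1; y <- ev$child2; t <- ev$time; pid <- ev$parent
      dtx <- t - node_time[x]; dty <- t - node_time[y]
      draws <- with_stream(streams$recomb,
                           c(rexp(2L, rate = dtx), rexp(2L, rate = dty)))
      rx <- recs[[x]]; ry <- recs[[y]]
      nb <- .recs_count(rx) + .recs_count(ry)
      rx <- .apply_branch(rx, draws[1L], draws[2L], w, prune)
      ry <- .apply_branch(ry, draws[3L], draws[4L], w, prune)
      segs <- .compare_records(rx, ry, w, t)
      if (length(segs$sample_a) > 0L) {
        sc <- sc + 1L
        seg_chunks[[sc]] <- segs
      }
      pooled <- list(l = c(rx$l, ry$l), r = c(rx$r, ry$r), s = c(rx$s, ry$s))
      if (merge) pooled <- .merge_records(pooled)
      recs[[pid]] <- pooled
      recs[x] <- list(NULL); recs[y] <- list(NULL)
      node_time[pid] <- t
      total_recs <- total_recs - nb + .recs_count(pooled)
      if (drop_empty && .recs_count(pooled) == 0L) .engine_remove(eng, pid)
      if (early_stop && total_recs <= 1L) break
    }
  }

  if (sc == 0L) {
    out <- tibble::tibble(sample_a = integer(0), sample_b = integer(0),
                          left_morgans = numeric(0), right_morgans = numeric(0),
                          length_morgans = numeric(0),
                          tmrca_generations = numeric(0),
                          group_a = character(0), group_b = character(0))
  } else {
    a <- unlist(lapply(seg_chunks, `[[`, "sample_a"), use.names = FALSE)
    b <- unlist(lapply(seg_chunks, `[[`, "sample_b"), use.names = FALSE)
    l <- unlist(lapply(seg_chunks, `[[`, "left"), use.names = FALSE)
    r <- unlist(lapply(seg_chunks, `[[`, "right"), use.names = FALSE)
    tm <- unlist(lapply(seg_chunks, `[[`, "tmrca"), use.names = FALSE)
    ord <- order(tm, a, b)
    out <- tibble::tibble(
      sample_a = a[ord], sample_b = b[ord],
      left_morgans = l[ord], right_morgans = r[ord],
      length_morgans = (l + r)[ord],
      tmrca_generations = tm[ord],
      group_a = groups[a[ord]], group_b = groups[b[ord]]
    )
  }
  out <- tibble::new_tibble(out, class = "ibd_sim")
  attr(out, "n_individuals") <- as.integer(n_individuals)
  attr(out, "n_haploids") <- n_hap
  attr(out, "w") <- w
  attr(out, "seed") <- as.integer(seed)
  attr(out, "variant") <- variant
  attr(out, "carriers") <- if (is.null(sweep)) integer(0) else carriers
  out
}

#' Naive simulation (exactness oracle)
#'
#' Runs [simulate_ibd()] with pruning and merging disabled, every lineage
#' retained, and the tree run to its root. With the same seed the output
#' segment set is exactly the set produced by the optimized variants.
#'
#' @inheritParams simulate_ibd
#' @param ... Passed to [simulate_ibd()].
#' @return A tibble of class `ibd_sim`.
#' @export
simulate_ibd_naive <- function(demog, n_individuals, w, sweep = NULL,
                               seed = NULL, ...) {
  simulate_ibd(demog, n_individuals, w, sweep = sweep, seed = seed,
               variant = "naive", ...)
}
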