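test_that("branch extension shrinks endpoints with one shared draw per side", {
  set.seed(1)
  ln <- lineage_state(list(1L, 2L, 3L), left = c(0.5, Inf, 0.02),
                      right = c(0.4, Inf, 0.03))
  out <- extend_branch(ln, t = 10, w = 1e-6, prune = FALSE)
  expect_equal(out$node_time, 10)
  expect_true(all(out$recs$l <= c(0.5, Inf, 0.02)))
  expect_true(all(out$recs$r <= c(0.4, Inf, 0.03)))
  # the record that started at Inf holds the raw shared draws; every other
  # endpoint is the minimum of its old value and that same draw
  dl <- out$recs$l[2]; dr <- out$recs$r[2]
  expect_equal(out$recs$l, pmin(c(0.5, Inf, 0.02), dl))
  expect_equal(out$recs$r, pmin(c(0.4, Inf, 0.03), dr))

  # pruning removes records that can no longer reach the threshold
  # short branch: Exponential(0.01) draws are huge, so only the record that
  # is already below threshold gets pruned
  ln2 <- lineage_state(list(1L, 2L), left = c(0.001, Inf),
                       right = c(0.001, Inf))
  out2 <- extend_branch(ln2, t = 0.01, w = 0.1, prune = TRUE)
  expect_equal(ibdlocus:::.recs_count(out2$recs), 1L)
  expect_equal(out2$recs$s, list(2L))

  expect_error(extend_branch(ln, t = 0, w = 1e-6), "exceed")
})

test_that("coalescence reports each detectable cross pair once and pools records", {
  set.seed(2)
  x <- lineage_state(list(c(1L, 2L)), id = 1L)   # merged record, two samples
  y <- lineage_state(list(3L), id = 2L)
  res <- coalesce_and_report(x, y, t = 50, w = 1e-9, id = 7L)
  segs <- res$segments
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$sample_a, c(1L, 2L))
  expect_equal(segs$sample_b, c(3L, 3L))
  # the merged record shares endpoints, so both pairs report the same segment
  expect_equal(segs$left[1], segs$left[2])
  expect_equal(segs$tmrca, c(50, 50))
  expect_equal(res$lineage$id, 7L)
  expect_equal(res$lineage$node_time, 50)
  expect_error(coalesce_and_report(x, x, 50, 1e-9))
})

test_that("pair segment length at fixed TMRCA t is Gamma(2, 2t)", {
  set.seed(3)
  t <- 100
  lens <- vapply(seq_len(10000L), function(i) {
    s <- coalesce_and_report(lineage_state(1L, id = 1L),
                             lineage_state(2L, id = 2L),
                             t = t, w = 1e-15)$segments
    s$left + s$right
  }, numeric(1))
  # each side is the minimum of two Exponential(t) draws, i.e. Exponential(2t);
  # sides are independent, so the sum is Gamma(shape 2, rate 2t)
  ks <- suppressWarnings(ks.test(lens, "pgamma", shape = 2, rate = 2 * t))
  expect_gt(ks$p.value, 0.01)
})

test_that("endpoint-sharing frequency matches v / (2u + v) per side", {
  set.seed(4)
  reps <- 3000L
  for (uv in list(c(50, 100), c(100, 100), c(100, 300))) {
    u <- uv[1]; v <- uv[2]
    hits <- 0L
    for (i in seq_len(reps)) {
      m <- coalesce_and_report(lineage_state(1L, id = 1L),
                               lineage_state(2L, id = 2L),
                               t = u, w = 1e-12, merge = FALSE)$lineage
      m <- extend_branch(m, t = u + v, w = 1e-12, prune = FALSE)
      hits <- hits + (m$recs$l[1] == m$recs$l[2])
    }
    p <- merge_probability(u, v)
    se <- sqrt(p * (1 - p) / reps)
    expect_lt(abs(hits / reps - p), 3 * se)
  }
})

test_that("pruning and merging are exact: all variants equal the naive oracle", {
  d <- build_scenario("bottleneck")
  base <- simulate_ibd(d, n_individuals = 200, w = 0.01, seed = 42,
                       variant = "naive")
  for (v in c("optimized", "prune_only", "merge_only")) {
    alt <- simulate_ibd(d, n_individuals = 200, w = 0.01, seed = 42,
                        variant = v, retain_empty = TRUE)
    expect_same_segments(alt, base)
  }
  # under a sweep as well
  m <- sweep_model(0.04, 0.5)
  base_s <- simulate_ibd(d, 50, w = 0.005, sweep = m, seed = 9,
                         carrier_count = 40, variant = "naive")
  opt_s <- simulate_ibd(d, 50, w = 0.005, sweep = m, seed = 9,
                        carrier_count = 40, variant = "optimized",
                        retain_empty = TRUE)
  expect_same_segments(opt_s, base_s)
  expect_gt(nrow(base_s), 0L)
})

test_that("simulated segment tables satisfy the output invariants", {
  d <- build_scenario("three_phase_growth")
  segs <- simulate_ibd(d, n_individuals = 150, w = 0.02, seed = 5)
  expect_s3_class(segs, "ibd_sim")
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$length_morgans >= 0.02))
  expect_equal(segs$length_morgans, segs$left_morgans + segs$right_morgans)
  expect_true(all(segs$sample_a < segs$sample_b))
  expect_true(all(segs$sample_b <= 300L))
  expect_true(all(segs$tmrca_generations > 0))
  expect_true(!is.unsorted(segs$tmrca_generations))
  # each unordered haplotype pair appears at most once
  expect_equal(anyDuplicated(segs[, c("sample_a", "sample_b")]), 0L)
  expect_equal(attr(segs, "n_haploids"), 300L)
  expect_equal(attr(segs, "variant"), "optimized")

  # reproducibility: same seed, same table
  again <- simulate_ibd(d, 150, w = 0.02, seed = 5)
  expect_identical(as.data.frame(tidy(again)), as.data.frame(tidy(segs)))

  # an unreachable threshold yields an empty table with the full schema
  none <- simulate_ibd(d, 10, w = 50, seed = 5, chrom_bounds = c(1.5, 1.5))
  expect_equal(nrow(none), 0L)
  expect_named(none, names(segs))
})

test_that("chromosome bounds cap the endpoint distances", {
  d <- build_scenario("constant", N_haploid = 500)
  segs <- simulate_ibd(d, 40, w = 0.01, seed = 8, chrom_bounds = c(0.3, 0.9))
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$left_morgans <= 0.3))
  expect_true(all(segs$right_morgans <= 0.9))
  expect_true(any(segs$left_morgans == 0.3))  # bound actually binds
})

test_that("replaying a precomputed event table reproduces the live run", {
  d <- build_scenario("constant", N_haploid = 2000)
  ev <- simulate_coalescent(d, 60L, seed = 13)
  live <- simulate_ibd(d, 30, w = 0.005, seed = 13, variant = "naive")
  replay <- simulate_ibd(d, 30, w = 0.005, seed = 13, variant = "naive",
                         events = ev)
  expect_same_segments(replay, live)
})

test_that("pair detection probability matches the integrated tail", {
  d <- build_scenario("constant", N_haploid = 1000)
  w <- 0.01
  # oracle: TMRCA ~ Exponential(1/N), detection tail exp(-2tw)(1 + 2tw)
  p_th <- integrate(function(t) dexp(t, 1 / 1000) * detectable_tail(w, 2 * t),
                    0, Inf, rel.tol = 1e-10)$value
  reps <- 8000L
  hits <- vapply(seq_len(reps), function(i) {
    nrow(simulate_ibd(d, 1, w = w, seed = 5000L + i)) > 0L
  }, logical(1))
  se <- sqrt(p_th * (1 - p_th) / reps)
  expect_lt(abs(mean(hits) - p_th), 3 * se)
})

test_that("sweep simulations respect carrier structure", {
  d <- build_scenario("constant", N_haploid = 10000)
  m <- sweep_model(0.04, 0.5)
  td <- denovo_time(m, d)
  segs <- simulate_ibd(d, 40, w = 1e-4, sweep = m, seed = 21,
                       carriers = 1:40)
  expect_equal(attr(segs, "carriers"), 1:40)
  cross <- segs$group_a != segs$group_b
  # no cross-group pair can find a common ancestor before the pooling time
  expect_true(all(segs$tmrca_generations[cross] >= td))
  expect_true(any(segs$group_a == "carrier" & segs$group_b == "carrier"))
})
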