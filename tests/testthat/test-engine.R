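test_that("switch statistic and engine configuration behave as documented", {
  expect_equal(switch_statistic(10, 1000), 1e-6)
  expect_equal(switch_statistic(100, 1000), 1e-3)
  expect_error(engine_config(switch_threshold = 0))
  expect_error(engine_config(force_wf = TRUE, force_kingman = TRUE))
})

test_that("one Wright-Fisher generation draws capped binomial pairings", {
  set.seed(7)
  # event count mean ~ choose(k,2)/N'
  k <- 30; N <- 5000
  reps <- 20000L
  counts <- vapply(seq_len(reps), function(i) {
    wf_generation_events(k, N)$m
  }, numeric(1))
  mu <- choose(k, 2) / N
  se <- sqrt(mu * (1 - 1 / N) / reps)
  expect_lt(abs(mean(counts) - mu), 3 * se)

  # pairings are disjoint lineage indices
  set.seed(8)
  ev <- list(m = 0L)
  while (ev$m == 0L) ev <- wf_generation_events(40, 100)
  expect_equal(dim(ev$pairs), c(ev$m, 2L))
  expect_true(all(ev$pairs %in% 1:40))
  expect_equal(anyDuplicated(as.vector(ev$pairs)), 0L)

  # the floor(k/2) cap binds and is reported when N' is tiny
  set.seed(9)
  expect_message(
    ev2 <- wf_generation_events(11, 2),
    "capped at floor\\(k/2\\) = 5"
  )
  expect_lte(ev2$m, 5L)
})

test_that("simulate_coalescent builds a valid binary tree", {
  d <- build_scenario("constant", N_haploid = 2000)
  H <- 64L
  tr <- simulate_coalescent(d, H, seed = 11)
  expect_equal(nrow(tr), H - 1L)
  expect_true(all(diff(tr$time) >= 0))
  expect_true(all(tr$time > 0))
  # parents are fresh ids H+1 .. 2H-1, in order
  expect_equal(tr$parent, H + seq_len(H - 1L))
  # every lineage except the root is a child exactly once
  kids <- c(tr$child1, tr$child2)
  expect_setequal(kids, seq_len(2L * H - 2L))
  expect_equal(anyDuplicated(kids), 0L)
  # children predate their parent
  expect_true(all(tr$child1 != tr$child2))
  expect_true(all(tr$subpop == "merged"))

  # until_k stops early
  tr20 <- simulate_coalescent(d, H, seed = 11, until_k = 20L)
  expect_equal(nrow(tr20), H - 20L)
  expect_equal(as.data.frame(tr20), as.data.frame(tr[seq_len(H - 20L), ]))
})

test_that("pair coalescence times are exponential in the Kingman regime", {
  d <- build_scenario("constant", N_haploid = 10000)
  cfg <- engine_config(force_kingman = TRUE)
  st <- rng_stream(101)
  t2 <- vapply(seq_len(2000L), function(i) {
    simulate_coalescent(d, 2L, config = cfg, tree_stream = st)$time
  }, numeric(1))
  ks <- suppressWarnings(ks.test(t2 / 10000, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("pair coalescence times are geometric in the Wright-Fisher regime", {
  d <- build_scenario("constant", N_haploid = 50)
  cfg <- engine_config(force_wf = TRUE)
  st <- rng_stream(202)
  t2 <- vapply(seq_len(4000L), function(i) {
    simulate_coalescent(d, 2L, config = cfg, tree_stream = st)$time
  }, numeric(1))
  # discrete generations: integer event times
  expect_true(all(t2 == round(t2)))
  expect_true(all(t2 >= 1))
  # geometric mean N with variance N^2(1 - 1/N)
  se <- sqrt(50^2 * (1 - 1 / 50) / 4000)
  expect_lt(abs(mean(t2) - 50), 3 * se)
})

test_that("the hybrid engine reproduces the expected event time at k = 40", {
  d <- build_scenario("constant", N_haploid = 10000)
  st <- rng_stream(303)
  reps <- 100L
  t40 <- vapply(seq_len(reps), function(i) {
    tr <- suppressMessages(
      simulate_coalescent(d, 10000L, tree_stream = st, until_k = 39L)
    )
    max(tr$time)
  }, numeric(1))
  theory <- expected_plus_time(n = 10000, k = 40, N = 10000)
  # sd of a sum of independent exponentials, plus slack for the
  # discrete-generation part of the hybrid walk
  sd_theory <- sqrt(sum((2 * 10000 / (40:10000 * (40:10000 - 1)))^2))
  tol <- 3 * sd_theory / sqrt(reps) + 2
  expect_lt(abs(mean(t40) - theory), tol)
})

test_that("numeric waiting-time inversion matches the closed form", {
  d <- demog_exp()
  f <- function(t) size_at(d, t)
  # the numeric walk accumulates rate at generation midpoints, so its
  # resolution is a small fraction of one generation
  for (e in c(0.05, 0.4, 1.3)) {
    expect_lt(abs(ibdlocus:::.wait_time_numeric(f, k = 6, t0 = 2.5, e = e) -
                    coalescent_wait_time(d, k = 6, t0 = 2.5, e = e)),
              0.05)
  }
})

test_that("the structured sweep phase keeps subpopulations separate", {
  d <- build_scenario("constant", N_haploid = 10000)
  m <- sweep_model(0.04, 0.5)
  td <- denovo_time(m, d)
  carriers <- 1:30
  tr <- simulate_coalescent(d, 60L, sweep = m, carriers = carriers, seed = 77)
  expect_equal(nrow(tr), 59L)
  pre <- tr[tr$time < td, ]
  expect_true(all(pre$subpop %in% c("carrier", "non_carrier")))
  expect_true(all(tr$subpop[tr$time >= td] == "merged"))
  # reconstruct subpopulation membership: no mixed coalescence before pooling
  side <- c(rep("carrier", 30), rep("non_carrier", 30))
  for (r in seq_len(nrow(tr))) {
    s1 <- side[tr$child1[r]]; s2 <- side[tr$child2[r]]
    if (tr$time[r] < td) {
      expect_identical(s1, s2)
      expect_identical(s1, tr$subpop[r])
      side[tr$parent[r]] <- s1
    } else {
      side[tr$parent[r]] <- "merged"
    }
  }
})
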