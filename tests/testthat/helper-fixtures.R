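# Shared fixtures and independent oracles.

# a two-epoch demography with backward growth in the first epoch
demog_exp <- function() {
  demography(data.frame(
    start = c(0, 20),
    end = c(20, Inf),
    size = c(1000, 1000 * exp(0.1 * 20)),
    rate = c(0.1, 0)
  ))
}

# random piecewise demography for property tests (uses session RNG)
random_demography <- function() {
  n_ep <- sample(2:4, 1)
  bounds <- sort(runif(n_ep - 1, 5, 400))
  starts <- c(0, bounds)
  ends <- c(bounds, Inf)
  sizes <- runif(n_ep, 500, 50000)
  rates <- c(runif(n_ep - 1, -0.04, 0.04), 0)
  # keep sizes >= 2 across finite epochs
  for (i in seq_len(n_ep - 1)) {
    while (sizes[i] * exp(rates[i] * (ends[i] - starts[i])) < 2) {
      rates[i] <- rates[i] / 2
    }
  }
  demography(data.frame(start = starts, end = ends, size = sizes, rate = rates))
}

# numeric quadrature of the pairwise coalescence-rate integral, split at
# epoch boundaries (integrate() misjudges its error across the kinks)
rate_integral <- function(demog, k, a, b) {
  cuts <- demog$start[demog$start > a & demog$start < b]
  pts <- c(a, sort(cuts), b)
  f <- function(u) choose(k, 2) / size_at(demog, u)
  sum(vapply(seq_len(length(pts) - 1L), function(i) {
    integrate(f, pts[i], pts[i + 1L],
              rel.tol = 1e-12, subdivisions = 5000L)$value
  }, numeric(1)))
}

# canonical data frame of a segment set for exact comparison across variants
segment_set <- function(segs) {
  df <- as.data.frame(tidy(segs))
  df[order(df$sample_a, df$sample_b), , drop = FALSE]
}

expect_same_segments <- function(a, b) {
  da <- segment_set(a); db <- segment_set(b)
  rownames(da) <- NULL; rownames(db) <- NULL
  expect_identical(da, db)
}
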