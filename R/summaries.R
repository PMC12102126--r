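# Summaries, broom-style methods, writers and plots for simulation results.

#' @export
print.ibd_sim <- function(x, ...) {
  cat(sprintf(
    "IBD segments around a focal locus: %d segments, %d individuals, w = %g M (%s)\n",
    nrow(x), attr(x, "n_individuals"), attr(x, "w"), attr(x, "variant")))
  NextMethod()
}

#' Tidy an IBD simulation result
#'
#' Returns the per-segment table as a plain tibble (one row per detectable
#' pairwise segment).
#'
#' @param x An `ibd_sim` result from [simulate_ibd()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ibd_sim <- function(x, ...) {
  tibble::as_tibble(unclass_ibd(x))
}

unclass_ibd <- function(x) {
  out <- x
  class(out) <- class(tibble::tibble())
  for (a in c("n_individuals", "n_haploids", "w", "seed", "variant",
              "carriers")) {
    attr(out, a) <- NULL
  }
  out
}

#' One-row summary of an IBD simulation
#'
#' @param x An `ibd_sim` result from [simulate_ibd()].
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, threshold, seed, segment count,
#'   haplotype pair count, IBD rate (segments per pair), and length
#'   percentiles (50, 80, 90, 95, 99) in Morgans.
#' @export
glance.ibd_sim <- function(x, ...) {
  n_hap <- attr(x, "n_haploids")
  n_pairs <- n_hap * (n_hap - 1) / 2
  q <- if (nrow(x) > 0) {
    quantile(x$length_morgans, c(.5, .8, .9, .95, .99), names = FALSE)
  } else {
    rep(NA_real_, 5L)
  }
  tibble::tibble(
    n_individuals = attr(x, "n_individuals"),
    n_haploids = n_hap,
    w = attr(x, "w"),
    seed = attr(x, "seed"),
    variant = attr(x, "variant"),
    n_segments = nrow(x),
    n_pairs = n_pairs,
    ibd_rate = nrow(x) / n_pairs,
    p50 = q[1], p80 = q[2], p90 = q[3], p95 = q[4], p99 = q[5]
  )
}

#' Plot the segment length distribution
#'
#' Empirical distribution of detectable segment lengths, with the detection
#' threshold marked.
#'
#' @param object An `ibd_sim` result from [simulate_ibd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ibd_sim <- function(object, ...) {
  df <- tidy.ibd_sim(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_morgans)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = attr(object, "w"), linetype = "dashed") +
    ggplot2::labs(x = "IBD segment length (Morgans)",
                  y = "empirical CDF",
                  title = sprintf("%d detectable segments, w = %g M",
                                  nrow(object), attr(object, "w")))
}

#' Write IBD segments to a TSV file
#'
#' Columns `sample_a`, `sample_b`, `left_morgans`, `right_morgans`,
#' `length_morgans`, `tmrca_generations`, `group_a`, `group_b`; floats with 6
#' significant digits; rows ordered by TMRCA then sample ids.
#'
#' @param segments An `ibd_sim` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ibd_tsv <- function(segments, path) {
  df <- as.data.frame(unclass_ibd(segments))
  for (col in c("left_morgans", "right_morgans", "length_morgans",
                "tmrca_generations")) {
    df[[col]] <- sprintf("%.6g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-replicate summary as a JSON-ready list
#'
#' @param segments An `ibd_sim` tibble.
#' @return A named list mirroring [glance.ibd_sim()], suitable for
#'   `jsonlite::write_json()`.
#' @export
ibd_summary <- function(segments) {
  g <- glance.ibd_sim(segments)
  lst <- as.list(g)
  lst$percentiles <- setNames(as.list(unlist(g[c("p50", "p80", "p90",
                                                 "p95", "p99")])),
                              c("50", "80", "90", "95", "99"))
  lst[c("p50", "p80", "p90", "p95", "p99")] <- NULL
  lst
}
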