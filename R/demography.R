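# Piecewise-exponential haploid effective population size N(t), with t in
# generations measured backward from the present (t = 0 is today).
#
# Each epoch covers [start, end) and has N(t) = size * exp(rate * (t - start)).
# `rate` is the *backward* exponential rate: rate < 0 means the population was
# smaller further in the past (i.e. it grew forward in time), rate > 0 means it
# was larger in the past. The final epoch extends to +Inf and must be constant
# (rate 0) so that every pair of lineages is guaranteed to coalesce.

#' Construct a demography from a table of epochs
#'
#' A demography is a tibble of contiguous epochs tiling `[0, Inf)`, each with a
#' haploid size at its recent boundary and a backward exponential growth rate.
#' All sizes are haploid: a sample of `n` diploid individuals corresponds to
#' `2 n` haploids, and population sizes follow the same convention.
#'
#' @param epochs A data frame with columns `start`, `end`, `size`, `rate`.
#'   Times are in generations before present; `size` is the haploid size at
#'   `start`; `rate` is the backward exponential rate, so
#'   `N(t) = size * exp(rate * (t - start))` within the epoch. A negative rate
#'   describes a population that grew exponentially forward in time.
#' @return A tibble of class `demography`.
#' @examples
#' demography(data.frame(start = 0, end = Inf, size = 20000, rate = 0))
#' @seealso [build_scenario()], [size_at()], [coalescent_wait_time()]
#' @export
demography <- function(epochs) {
  epochs <- tibble::as_tibble(epochs)
  required <- c("start", "end", "size", "rate")
  if (!all(required %in% names(epochs))) {
    stop("epochs must have columns start, end, size, rate", call. = FALSE)
  }
  epochs <- epochs[required]
  epochs <- epochs[order(epochs$start), , drop = FALSE]
  out <- tibble::new_tibble(epochs, class = "demography")
  validate_demography(out)
  out
}

validate_demography <- function(demog) {
  e <- demog
  if (nrow(e) < 1L) stop("demography needs at least one epoch", call. = FALSE)
  if (e$start[1L] != 0) stop("first epoch must start at 0", call. = FALSE)
  if (!is.infinite(e$end[nrow(e)])) {
    stop("last epoch must extend to +Inf", call. = FALSE)
  }
  if (any(e$start >= e$end)) {
    stop("each epoch must have start < end", call. = FALSE)
  }
  if (nrow(e) > 1L && any(abs(e$end[-nrow(e)] - e$start[-1L]) > 1e-9)) {
    stop("epochs must be contiguous (end of one equals start of the next)",
         call. = FALSE)
  }
  if (e$rate[nrow(e)] != 0) {
    stop("last (ancestral) epoch must be constant: rate 0, so that the ",
         "pairwise coalescence-rate integral diverges", call. = FALSE)
  }
  # minimum size within an epoch is at whichever end the rate points down to
  start_size <- e$size
  end_size <- ifelse(is.finite(e$end),
                     e$size * exp(e$rate * (e$end - e$start)), e$size)
  if (any(pmin(start_size, end_size) < 2)) {
    stop("haploid size must be >= 2 throughout every epoch", call. = FALSE)
  }
  invisible(demog)
}

#' Evaluate the haploid effective population size at a time in the past
#'
#' @param demog A [demography()].
#' @param t Generations before present (vectorized, `t >= 0`).
#' @return Haploid size(s) `N(t)`.
#' @examples
#' d <- build_scenario("constant", N_haploid = 10000)
#' size_at(d, c(0, 100, 1e6))
#' @export
size_at <- function(demog, t) {
  stopifnot(inherits(demog, "demography"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  idx <- findInterval(t, demog$start)
  demog$size[idx] * exp(demog$rate[idx] * (t - demog$start[idx]))
}

#' Build a demography from a forward-in-time growth description
#'
#' Converts phases described the way demographers usually state them (the
#' population grew forward in time at given exponential rates) into the
#' backward-time epoch representation used everywhere else in the package.
#'
#' @param ancestral_size Haploid size before the oldest phase.
#' @param phase_ends Increasing vector of phase boundaries in generations
#'   before present; phase `j` spans `(phase_ends[j-1], phase_ends[j]]` with
#'   `phase_ends[0] = 0`.
#' @param forward_rates Forward per-generation exponential growth rate of each
#'   phase (same length as `phase_ends`).
#' @return A [demography()].
#' @export
forward_growth_demography <- function(ancestral_size, phase_ends, forward_rates) {
  stopifnot(length(phase_ends) == length(forward_rates),
            all(diff(phase_ends) > 0), all(phase_ends > 0))
  nph <- length(phase_ends)
  # size at the older boundary of each phase, found from the ancestral size
  bound_size <- numeric(nph + 1L)
  bound_size[nph + 1L] <- ancestral_size
  starts <- c(0, phase_ends[-nph])
  for (j in rev(seq_len(nph))) {
    bound_size[j] <- bound_size[j + 1L] *
      exp(forward_rates[j] * (phase_ends[j] - starts[j]))
  }
  demography(data.frame(
    start = c(starts, phase_ends[nph]),
    end   = c(phase_ends, Inf),
    size  = c(bound_size[seq_len(nph)], ancestral_size),
    rate  = c(-forward_rates, 0)
  ))
}

#' Build one of the built-in demographic scenarios
#'
#' Three scenario families are provided: a constant-size population; a
#' population bottleneck (an ancestral population that grew exponentially but
#' suffered an instantaneous reduction in size twenty generations before the
#' present); and three phases of exponential growth from a smaller ancestral
#' population (a UK-like growth history). The bottleneck and growth scenarios
#' are qualitative stand-ins parameterized here with explicit defaults; every
#' rate, size and change time can be overridden.
#'
#' @param name One of `"constant"`, `"bottleneck"`, `"three_phase_growth"`.
#' @param ... Scenario parameters:
#'   * `constant`: `N_haploid` (default 20000).
#'   * `bottleneck`: `N_ancestral` (haploids, default 20000 = 10,000
#'     individuals), `growth_rate` (forward, default 0.02), `growth_start`
#'     (generations ago growth began, default 300), `bottleneck_time`
#'     (default 20), `bottleneck_strength` (size multiplier at the crash,
#'     default 0.01).
#'   * `three_phase_growth`: `N_ancestral` (default 10000 haploids = 5000
#'     individuals), `phase_ends` (default `c(10, 100, 300)`),
#'     `forward_rates` (default `c(0.25, 0.05, 0.01)`).
#' @return A [demography()].
#' @examples
#' build_scenario("bottleneck")
#' @export
build_scenario <- function(name = c("constant", "bottleneck", "three_phase_growth"),
                           ...) {
  name <- match.arg(name)
  p <- list(...)
  take <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default
  switch(
    name,
    constant = {
      N <- take("N_haploid", 20000)
      demography(data.frame(start = 0, end = Inf, size = N, rate = 0))
    },
    bottleneck = {
      N_anc <- take("N_ancestral", 20000)
      g     <- take("growth_rate", 0.02)
      t_g   <- take("growth_start", 300)
      t_b   <- take("bottleneck_time", 20)
      f     <- take("bottleneck_strength", 0.01)
      stopifnot(t_b > 0, t_g > t_b, g >= 0, f > 0)
      N_pre  <- N_anc * exp(g * (t_g - t_b))   # just before the crash (older side)
      N_post <- N_pre * f                      # just after the crash (recent side)
      N_now  <- N_post * exp(g * t_b)
      demography(data.frame(
        start = c(0, t_b, t_g),
        end   = c(t_b, t_g, Inf),
        size  = c(N_now, N_pre, N_anc),
        rate  = c(-g, -g, 0)
      ))
    },
    three_phase_growth = {
      forward_growth_demography(
        ancestral_size = take("N_ancestral", 10000),
        phase_ends     = take("phase_ends", c(10, 100, 300)),
        forward_rates  = take("forward_rates", c(0.25, 0.05, 0.01))
      )
    }
  )
}

# integral of choose(k,2)/N(u) over [a, b] where [a, b] lies inside epoch i
.epoch_rate_integral <- function(demog, i, k, a, b) {
  S <- demog$size[i]; r <- demog$rate[i]; s0 <- demog$start[i]
  ck2 <- k * (k - 1) / 2
  if (r == 0) {
    ck2 * (b - a) / S
  } else {
    ck2 * (exp(-r * (a - s0)) - exp(-r * (b - s0))) / (S * r)
  }
}

#' Invert the cumulative pairwise coalescence rate
#'
#' Given `k` uncoalesced lineages at time `t0` and a unit-exponential deviate
#' `e`, returns the waiting time of the next coalescent event under the
#' time-inhomogeneous Kingman model: the smallest `t > t0` with
#' `integral from t0 to t of choose(k,2) / N(u) du = e`. This is the post-hoc
#' time-rescaling of a constant-size coalescent to a varying `N(t)`, computed
#' in closed form per epoch and chained across epoch boundaries.
#'
#' @param demog A [demography()].
#' @param k Number of uncoalesced lineages (`k >= 2`).
#' @param t0 Current time in generations (`t0 >= 0`).
#' @param e Unit-exponential deviate(s) (`e > 0`); vectorized.
#' @return Event time(s) in generations, `> t0`.
#' @examples
#' d <- build_scenario("constant", N_haploid = 10000)
#' coalescent_wait_time(d, k = 2, t0 = 0, e = 1)  # 10000 generations
#' @export
coalescent_wait_time <- function(demog, k, t0, e) {
  stopifnot(inherits(demog, "demography"), k >= 2, t0 >= 0, all(e > 0))
  vapply(e, function(e1) .wait_time_scalar(demog, k, t0, e1), numeric(1))
}

.wait_time_scalar <- function(demog, k, t0, e) {
  i <- findInterval(t0, demog$start)
  cur <- t0
  repeat {
    epoch_end <- demog$end[i]
    full <- if (is.finite(epoch_end)) {
      .epoch_rate_integral(demog, i, k, cur, epoch_end)
    } else {
      Inf
    }
    if (e <= full) {
      return(.epoch_solve(demog, i, k, cur, e))
    }
    e <- e - full
    cur <- epoch_end
    i <- i + 1L
  }
}

# solve within epoch i: integral from a to t equals e (guaranteed attainable)
.epoch_solve <- function(demog, i, k, a, e) {
  S <- demog$size[i]; r <- demog$rate[i]; s0 <- demog$start[i]
  ck2 <- k * (k - 1) / 2
  if (r == 0) {
    a + e * S / ck2
  } else {
    ea <- exp(-r * (a - s0))
    et <- ea - e * S * r / ck2
    s0 - log(et) / r
  }
}

#' Read or write a demography as YAML or JSON
#'
#' The on-disk form is either a list of epochs
#' (`epochs: [{start, end, size, rate}, ...]`, with the final `end` given as
#' `.inf`/`"Inf"`) or a built-in scenario reference
#' (`scenario: bottleneck` plus optional `params:`). The format is chosen by
#' file extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File path.
#' @return `read_demography()` returns a [demography()];
#'   `write_demography()` returns `path` invisibly.
#' @export
read_demography <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  demography_from_list(doc)
}

demography_from_list <- function(doc) {
  if (!is.null(doc$scenario)) {
    return(do.call(build_scenario, c(list(name = doc$scenario),
                                     as.list(doc$params))))
  }
  ep <- doc$epochs
  if (is.null(ep)) stop("demography document needs 'epochs' or 'scenario'",
                        call. = FALSE)
  if (is.data.frame(ep)) {
    ep[] <- lapply(ep, function(col) suppressWarnings(as.numeric(col)))
    return(demography(ep))
  }
  rows <- lapply(ep, function(r) {
    vapply(r[c("start", "end", "size", "rate")],
           function(v) suppressWarnings(as.numeric(v)), numeric(1))
  })
  demography(as.data.frame(do.call(rbind, rows)))
}

#' @rdname read_demography
#' @param demog A [demography()] to serialize.
#' @export
write_demography <- function(demog, path) {
  stopifnot(inherits(demog, "demography"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ep <- as.data.frame(demog)
    ep$end <- ifelse(is.finite(ep$end), as.character(ep$end), "Inf")
    jsonlite::write_json(list(epochs = ep), path, auto_unbox = TRUE, digits = NA)
  } else {
    ep <- lapply(seq_len(nrow(demog)), function(i) {
      list(start = demog$start[i], end = demog$end[i],
           size = demog$size[i], rate = demog$rate[i])
    })
    yaml::write_yaml(list(epochs = ep), path)
  }
  invisible(path)
}

#' Plot a demography
#'
#' Haploid effective size against generations before present, log-scaled size
#' axis.
#'
#' @param object A [demography()].
#' @param t_max Oldest time to display (default: twice the last epoch start,
#'   at least 500 generations).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demography <- function(object, t_max = NULL, ...) {
  if (is.null(t_max)) t_max <- max(500, 2 * max(object$start))
  t <- seq(0, t_max, length.out = 512)
  df <- tibble::tibble(t = t, N = size_at(object, t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$N)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present",
                  y = "haploid effective size N(t)")
}
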