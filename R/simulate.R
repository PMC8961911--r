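#' Exact event-driven simulation of the (phase, count) process
#'
#' Simulates one trajectory of \eqn{\{X_t, M_t\}} by the Gillespie
#' algorithm: at each state the enabled transitions (switching, phase
#' advance, birth on completion of phase L, per-molecule death) compete
#' with their exponential clocks.  The count is unbounded (no
#' truncation is applied during simulation).  Reproducibility is
#' governed by R's RNG state (`set.seed()`).
#'
#' @param p an [params()] object.
#' @param spec model specification (defaults to `p$spec`).
#' @param t_max simulated horizon (> 0).
#' @param m0 initial count (default 0).
#' @param x0 initial phase; default `NULL` draws it from
#'   [stationary_phase_distribution()].
#' @return a data.frame with columns `time`, `phase`, `count`: the
#'   right-continuous jump chain (first row is the initial state).
#' @examples
#' sp <- model_spec(2, fixed = c(mu = 0))
#' p <- params(sp, q_on = 0.1, q_off = 0.2, lambdas = c(2, 1), mu = 0)
#' set.seed(1)
#' path <- simulate_path(p, t_max = 100)
#' @export
simulate_path <- function(p, spec = p$spec, t_max, m0 = 0L, x0 = NULL) {
  stopifnot(inherits(p, "onoffseq_params"), t_max > 0, m0 >= 0)
  if (is.null(x0)) {
    pi0 <- stationary_phase_distribution(p, spec)
    x0 <- sample(spec$E, 1L, prob = pi0)
  }
  res <- simulate_grid_cpp(p$q_on, p$q_off, p$lambdas, p$mu,
                           spec$has_switch, 1L, t_max, as.integer(m0),
                           as.integer(x0), TRUE)
  data.frame(time = res$times, phase = res$phase, count = res$count)
}

#' Simulate one gridded count series
#'
#' Simulates a path and records the count at the observation times
#' `0, Delta, ..., n * Delta`; the continuous path is discarded.
#'
#' @inheritParams simulate_path
#' @param n number of lags (the series has `n + 1` observations).
#' @param delta observation lag (> 0).
#' @param series_id label attached to the series.
#' @return an object of class `"count_series"`: list with integer
#'   `counts` (length `n + 1`), `delta` and `series_id`.
#' @export
sample_series <- function(p, spec = p$spec, n, delta = 1, m0 = 0L,
                          x0 = NULL, series_id = "s1") {
  stopifnot(inherits(p, "onoffseq_params"), n >= 0, delta > 0, m0 >= 0)
  if (is.null(x0)) {
    pi0 <- stationary_phase_distribution(p, spec)
    x0 <- sample(spec$E, 1L, prob = pi0)
  }
  counts <- if (n == 0L) as.integer(m0) else
    simulate_grid_cpp(p$q_on, p$q_off, p$lambdas, p$mu, spec$has_switch,
                      as.integer(n), delta, as.integer(m0),
                      as.integer(x0), FALSE)$counts
  structure(list(counts = as.integer(counts), delta = delta,
                 series_id = series_id),
            class = "count_series")
}

#' Simulate a dataset of independent count series
#'
#' Simulates `N` independent series at a common lag.  Each series draws
#' its RNG substream from a per-series seed derived from the root seed
#' and the series index, so enlarging `N` leaves earlier series
#' unchanged.
#'
#' @inheritParams sample_series
#' @param N number of independent series (cells).
#' @param lengths single `n` broadcast to all series, or an
#'   integer vector of per-series lag counts `n_k`.
#' @param seed optional root seed; `NULL` uses the current RNG state
#'   (with sequential, still independent, substreams).
#' @param x0 initial phase for every series; default `NULL` draws each
#'   from the stationary phase law (the model's own assumption).
#'   `x0 = 1` starts every cell with the switch on, a condition of
#'   interest because it induces an order-1/n upward bias in the
#'   estimated switch-on rate (see the methods vignette).
#' @return an object of class `"observation_set"`: list with `series`
#'   (list of `"count_series"`) and `delta`.
#' @export
sample_dataset <- function(p, spec = p$spec, N, lengths, delta = 1,
                           m0 = 0L, seed = NULL, x0 = NULL) {
  stopifnot(inherits(p, "onoffseq_params"), N >= 1)
  lengths <- as.integer(rep(lengths, length.out = N))
  series <- vector("list", N)
  for (k in seq_len(N)) {
    if (!is.null(seed)) set.seed(series_seed(seed, k))
    series[[k]] <- sample_series(p, spec, n = lengths[k], delta = delta,
                                 m0 = m0, x0 = x0,
                                 series_id = sprintf("s%04d", k))
  }
  structure(list(series = series, delta = delta),
            class = "observation_set")
}

# Per-series substream seed: mixes the root seed with the series index
# so datasets extend without reshuffling (kept below 2^31).
series_seed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + k * 12820163) %% 2147483647
}

#' @export
print.observation_set <- function(x, ...) {
  n_k <- vapply(x$series, function(s) length(s$counts) - 1L, integer(1))
  cat("observation set: N =", length(x$series), "series, delta =",
      x$delta, "\n  lags n_k:", if (length(unique(n_k)) == 1L)
        unique(n_k) else paste(range(n_k), collapse = "-"),
      " max count:", max(vapply(x$series, function(s) max(s$counts),
                                integer(1))), "\n")
  invisible(x)
}

#' Sample inter-birth times from the geometric-sum representation
#'
#' The time `T` between consecutive births starts in the on state and
#' decomposes as a geometric sum: with probability
#' \eqn{p = \lambda_1 / (\lambda_1 + q_{off})} the first phase completes
#' before the switch turns off, else one off/on loop (an
#' Exp(\eqn{\lambda_1 + q_{off}}) race lost plus an Exp(\eqn{q_{on}})
#' off period) is inserted; the final passage is
#' Exp(\eqn{\lambda_1 + q_{off}}) followed by the remaining phases
#' Exp(\eqn{\lambda_2}), ..., Exp(\eqn{\lambda_L}).  Sampling this
#' representation directly is far cheaper than simulating the full
#' process.
#'
#' @param p an [params()] object (switch model; `q_off = 0` reduces to
#'   the plain hypoexponential of the `L` phases).
#' @param B number of samples.
#' @return numeric vector of `B` inter-birth times.
#' @export
sample_interbirth_times <- function(p, B) {
  stopifnot(inherits(p, "onoffseq_params"), B >= 1)
  if (!p$spec$has_switch)
    stop("inter-birth sampling is defined for the switch model; ",
         "use q_off = 0 for an always-on process")
  if (p$q_off > 0 && p$q_on <= 0)
    stop("q_off > 0 with q_on = 0: the off period never ends ",
         "(infinite inter-birth time)")
  lam1 <- p$lambdas[1L]
  rate1 <- lam1 + p$q_off
  prob <- lam1 / rate1
  G <- stats::rgeom(B, prob) + 1L        # support {1, 2, ...}
  loops <- G - 1L
  tot <- numeric(B)
  has <- loops > 0L
  if (any(has)) {
    # sum of 'loops' iid Exp(rate1) is Gamma(loops, rate1); same for q_on
    tot[has] <- stats::rgamma(sum(has), shape = loops[has], rate = rate1) +
      stats::rgamma(sum(has), shape = loops[has], rate = p$q_on)
  }
  final <- stats::rexp(B, rate1)
  if (p$spec$L >= 2L)
    for (i in 2:p$spec$L) final <- final + stats::rexp(B, p$lambdas[i])
  tot + final
}
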