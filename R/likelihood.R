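#' Initial hidden-phase weights
#'
#' The likelihood conditions on the first observed count `m0`; only the
#' hidden phase needs an initial law, which the model fixes at the
#' stationary distribution of the marginal phase chain.  The count
#' argument is accepted for interface symmetry but does not alter the
#' weights (it determines only the level at which the forward mass is
#' placed).
#'
#' @param p an [params()] object.
#' @param spec model specification (defaults to `p$spec`).
#' @param m0 first observed count (>= 0).
#' @return probability vector over the phase set `E`.
#' @export
initial_phase_weights <- function(p, spec = p$spec, m0 = 0L) {
  stopifnot(m0 >= 0)
  stationary_phase_distribution(p, spec)
}

#' Log-likelihood of one count series
#'
#' Evaluates the probability of the observed counts
#' `m_1, ..., m_n` given `m_0` by summing over all hidden phase paths:
#' a forward recursion propagates the phase-indexed vector
#' \eqn{\alpha_i(x) = \sum_{x'} \alpha_{i-1}(x')\,
#' p_{x'x}(m_{i-1}, m_i; \Delta)} with per-step renormalization
#' (accumulating log scale factors), so the result is exact up to the
#' kernel approximation and never underflows.
#'
#' @param kernel a [erlang_kernel()] result (its lag must equal the
#'   series lag).
#' @param p,spec parameters and model specification.
#' @param series a `"count_series"`.
#' @return the log-probability; `-Inf` if the series has probability
#'   zero under the model (e.g. a decreasing count with `mu = 0`).
#' @export
series_loglik <- function(kernel, p, spec = p$spec, series) {
  stopifnot(inherits(kernel, "transition_kernel"),
            inherits(series, "count_series"))
  if (abs(kernel$delta - series$delta) > 1e-12)
    stop("kernel lag (", kernel$delta, ") does not match series lag (",
         series$delta, ")")
  C <- kernel$state_space$C
  if (max(series$counts) > C)
    stop("series '", series$series_id, "' has count ",
         max(series$counts), " > truncation C = ", C,
         "; enlarge the truncation level")
  pi0 <- initial_phase_weights(p, spec, series$counts[1L])
  forward_loglik_cpp(kernel$P, kernel$state_space$n_phases,
                     series$counts, matrix(pi0, 1L), FALSE)
}

#' Brute-force likelihood by hidden-path enumeration
#'
#' Literal transcription of the conditional likelihood: sums
#' \eqn{\pi(x_0) \prod_i p_{x_{i-1} x_i}(m_{i-1}, m_i; \Delta)} over
#' every phase path \eqn{(x_0, ..., x_n) \in E^{n+1}}.  Exponential in
#' `n`; serves as the independent oracle for [series_loglik()] on tiny
#' instances and refuses more than 1e6 paths.
#'
#' @inheritParams series_loglik
#' @return the log-probability (`-Inf` for an impossible series).
#' @export
brute_force_loglik <- function(kernel, p, spec = p$spec, series) {
  stopifnot(inherits(kernel, "transition_kernel"),
            inherits(series, "count_series"))
  E <- spec$E
  nE <- length(E)
  counts <- series$counts
  n <- length(counts) - 1L
  if (nE^(n + 1L) > 1e6)
    stop("path enumeration refused: ", nE^(n + 1L), " phase paths")
  ss <- kernel$state_space
  pi0 <- initial_phase_weights(p, spec, counts[1L])
  paths <- as.matrix(expand.grid(rep(list(seq_len(nE)), n + 1L)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    path <- paths[r, ]
    prob <- pi0[path[1L]]
    if (n > 0) for (i in seq_len(n)) {
      from <- counts[i] * nE + path[i]
      to <- counts[i + 1L] * nE + path[i + 1L]
      prob <- prob * kernel$P[from, to]
    }
    total <- total + prob
  }
  if (total <= 0) -Inf else unname(log(total))
}

#' Total log-likelihood of a dataset
#'
#' Sum of per-series log-likelihoods over the `N` independent series
#' (series lengths may differ).  The transition kernel is built once
#' per parameter vector and shared across series.
#'
#' For a pure-birth model (`mu = 0`) the truncated generator is
#' level-homogeneous and counts are non-decreasing, so the kernel entry
#' from count `m` to `m + j` equals the entry from 0 to `j` and is
#' unaffected by the truncation whenever `j` stays below it.  The
#' evaluation then uses a kernel built on the small window
#' `0..(max increment + 2)` indexed by count increments -- an exact
#' algebraic shortcut, not an approximation: it returns the same value
#' as the full kernel at any truncation above the largest observed
#' count (see the methods vignette).
#'
#' @param p an [params()] object.
#' @param spec model specification (defaults to `p$spec`).
#' @param data an `"observation_set"`.
#' @param C population truncation level (must exceed every observed
#'   count for the likelihood to be well defined; see
#'   [choose_truncation()]).
#' @param ell Erlang stages (power of two).
#' @return an object of class `"onoffseq_loglik"`: list with `value`,
#'   `per_series`, `theta` and `settings`.
#' @export
total_loglik <- function(p, spec = p$spec, data, C, ell = 2048L) {
  stopifnot(inherits(p, "onoffseq_params"),
            inherits(data, "observation_set"),
            length(data$series) >= 1L)
  counts_max <- max(vapply(data$series, function(s) max(s$counts),
                           integer(1)))
  if (counts_max > C)
    stop("observed count ", counts_max, " exceeds truncation C = ", C,
         "; enlarge C")
  pi0 <- matrix(stationary_phase_distribution(p, spec), 1L)
  pure_birth <- p$mu == 0 && counts_max < C
  if (pure_birth) {
    inc_max <- max(0L, vapply(data$series, function(s)
      if (length(s$counts) > 1L) max(diff(s$counts)) else 0L, integer(1)))
    C_eff <- max(inc_max + 2L, 2L)
  } else {
    C_eff <- C
  }
  gen <- assemble_generator(build_blocks(p, spec, C_eff))
  ker <- erlang_kernel(gen, data$delta, ell)
  nE <- gen$state_space$n_phases
  per <- forward_loglik_set_cpp(ker$P, nE,
                                lapply(data$series, `[[`, "counts"),
                                pi0, pure_birth)
  structure(list(value = sum(per), per_series = per,
                 theta = theta_vector(p),
                 settings = list(C = C, ell = ell, delta = data$delta)),
            class = "onoffseq_loglik")
}

#' @export
print.onoffseq_loglik <- function(x, ...) {
  cat(sprintf("log-likelihood: %.1f over %d series (C = %s, ell = %d)\n",
              x$value, length(x$per_series), x$settings$C,
              x$settings$ell))
  invisible(x)
}
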