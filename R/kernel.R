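#' Resolvent kernel of the truncated chain
#'
#' Distribution of the state after an exponential time with rate `eta`:
#' \eqn{\Pi_\eta = \eta (\eta I - Q)^{-1}}, computed by one dense
#' factorization of \eqn{\eta I - Q} applied to all `D` right-hand
#' sides.  Rows sum to one; round-off negatives above `-1e-12` are
#' clipped to zero and the row renormalized, anything below that raises
#' an error.
#'
#' @param gen an [assemble_generator()] result.
#' @param eta exponential rate (> 0).
#' @return a row-stochastic `D x D` matrix.
#' @export
resolvent_kernel <- function(gen, eta) {
  stopifnot(inherits(gen, "qbd_generator"), eta > 0)
  D <- gen$state_space$D
  A <- diag(eta, D) - gen$Q
  P <- tryCatch(eta * solve(A), error = function(e)
    stop("resolvent solve failed; is Q a proper generator? ",
         conditionMessage(e)))
  kernel_power_cpp(P, 1L, 1e-12)
}

#' Erlangization approximation of the lag-Delta transition kernel
#'
#' Approximates the transition probabilities
#' \eqn{p_{xx'}(m, m'; \Delta)} of the truncated quasi birth-death
#' chain by the `ell`-step resolvent power
#' \eqn{(\Pi_{\ell/\Delta})^{\ell}}: the state distribution at an
#' Erlang(`ell`, `ell/Delta`) time, which concentrates on `Delta` as
#' `ell` grows (error of order `1/ell`).  `ell` is restricted to powers
#' of two so the power is computed by exact repeated squaring (11
#' multiplications at the default `ell = 2048`), with rows
#' renormalized after every squaring.
#'
#' @param gen an [assemble_generator()] result.
#' @param delta observation lag (> 0).
#' @param ell number of Erlang stages; a power of two.
#' @return an object of class `"transition_kernel"`: list with the
#'   row-stochastic matrix `P`, `delta`, `ell` and the `state_space`.
#' @export
erlang_kernel <- function(gen, delta, ell = 2048L) {
  stopifnot(inherits(gen, "qbd_generator"), delta > 0)
  ell <- as.integer(ell)
  if (ell < 1L || bitwAnd(ell, ell - 1L) != 0L)
    stop("ell must be a power of two >= 1 (got ", ell, ")")
  Pi <- resolvent_kernel(gen, ell / delta)
  P <- if (ell == 1L) Pi else kernel_power_cpp(Pi, ell, 1e-12)
  out <- list(P = P, delta = delta, ell = ell,
              state_space = gen$state_space)
  class(out) <- "transition_kernel"
  out
}

#' Matrix-exponential oracle by uniformization
#'
#' Independent reference for the lag-Delta transition probabilities:
#' \eqn{e^{Q\Delta}} evaluated by uniformization (randomization).  With
#' \eqn{\bar\lambda = \max_i |Q_{ii}|} and
#' \eqn{\bar P = I + Q/\bar\lambda}, sums Poisson(\eqn{\bar\lambda
#' \Delta})-weighted powers of \eqn{\bar P} until the neglected tail
#' mass is below `1e-12`.  Intended for validation on small state
#' spaces; the production path is [erlang_kernel()].
#'
#' @param gen an [assemble_generator()] result.
#' @param delta time lag (>= 0).
#' @return a row-stochastic `D x D` matrix.
#' @export
matrix_exponential_oracle <- function(gen, delta) {
  stopifnot(inherits(gen, "qbd_generator"), delta >= 0)
  Q <- gen$Q
  D <- nrow(Q)
  if (delta == 0) return(diag(D))
  lam <- max(abs(diag(Q)))
  if (lam == 0) return(diag(D))
  Pbar <- diag(D) + Q / lam
  rate <- lam * delta
  # Poisson weights beyond k_max carry < 1e-12 mass
  k_max <- max(10, ceiling(rate + 12 * sqrt(rate) + 12))
  w <- stats::dpois(0:k_max, rate)
  out <- w[1L] * diag(D)
  term <- diag(D)
  for (k in seq_len(k_max)) {
    term <- term %*% Pbar
    out <- out + w[k + 1L] * term
  }
  out / rowSums(out)
}

#' Choose the population truncation level
#'
#' Selects the smallest truncation `C` from a doubling schedule
#' starting at `max(2 * data_max, 20)` such that, under the kernel
#' built at that truncation, the total probability of reaching the top
#' 10\% of levels within one lag `Delta` from any level up to
#' `data_max` stays below `epsilon`.  This operationalizes the
#' requirement that one-lag mass above the truncation be negligible.
#'
#' @param p an [params()] object.
#' @param spec model specification (defaults to `p$spec`).
#' @param data_max largest count the kernel must serve (observed or
#'   initial).
#' @param delta observation lag.
#' @param epsilon tolerated one-lag escape probability (default 1e-8).
#' @param ell Erlang stages for the trial kernels.
#' @return integer truncation level `C >= data_max + 1`.
#' @export
choose_truncation <- function(p, spec = p$spec, data_max, delta,
                              epsilon = 1e-8, ell = 2048L) {
  stopifnot(inherits(p, "onoffseq_params"),
            epsilon > 0, epsilon < 1, data_max >= 0, delta > 0)
  C <- max(2L * as.integer(data_max), 20L)
  repeat {
    if (C > 1e5)
      stop("truncation search exceeded C = 1e5; check the parameter ",
           "scale relative to the lag")
    gen <- assemble_generator(build_blocks(p, spec, C))
    ker <- erlang_kernel(gen, delta, ell)
    nE <- gen$state_space$n_phases
    top <- floor(0.9 * C)
    rows <- seq_len((min(data_max, C - 1L) + 1L) * nE)
    cols <- (top * nE + 1L):gen$state_space$D
    escape <- max(rowSums(ker$P[rows, cols, drop = FALSE]))
    if (escape < epsilon) return(max(C, as.integer(data_max) + 1L))
    C <- 2L * C
  }
}
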