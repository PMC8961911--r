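#' Closed-form mean of the inter-birth time
#'
#' From Wald's equation applied to the geometric-sum representation of
#' the inter-birth time `T` (off/on loops followed by the `L`-phase
#' final passage):
#' \deqn{E[T] = \sum_{i=1}^{L} 1/\lambda_i + q_{off} / (q_{on} \lambda_1).}
#'
#' @param p an [params()] object.
#' @return expected inter-birth time (time units).
#' @examples
#' sp <- model_spec(2, fixed = c(mu = 0))
#' expected_interbirth(params(sp, q_on = 0.1, q_off = 0.2,
#'                            lambdas = c(2, 1)))  # 2.5
#' @export
expected_interbirth <- function(p) {
  stopifnot(inherits(p, "onoffseq_params"))
  if (p$q_off > 0 && p$q_on <= 0)
    stop("q_off > 0 with q_on = 0: the mean inter-birth time is infinite")
  loop <- if (p$q_off > 0) p$q_off / (p$q_on * p$lambdas[1L]) else 0
  sum(1 / p$lambdas) + loop
}

#' Closed-form variance of the inter-birth time
#'
#' Wald's equation for the variance of the geometric sum gives
#' \deqn{Var[T] = \sum_{i=1}^{L} 1/\lambda_i^2 +
#'   (2 q_{off} \lambda_1 + q_{off}^2 + 2 q_{on} q_{off}) /
#'   (\lambda_1^2 q_{on}^2).}
#'
#' @param p an [params()] object.
#' @return variance of the inter-birth time (squared time units).
#' @export
var_interbirth <- function(p) {
  stopifnot(inherits(p, "onoffseq_params"))
  if (p$q_off > 0 && p$q_on <= 0)
    stop("q_off > 0 with q_on = 0: the inter-birth variance is infinite")
  loop <- if (p$q_off > 0)
    (2 * p$q_off * p$lambdas[1L] + p$q_off^2 + 2 * p$q_on * p$q_off) /
      (p$lambdas[1L]^2 * p$q_on^2) else 0
  sum(1 / p$lambdas^2) + loop
}

#' Probability that a started birth completes before the switch turns off
#'
#' The loop counter of the geometric-sum representation is geometric on
#' \{1, 2, ...\} with success probability
#' \eqn{p = \lambda_1 / (\lambda_1 + q_{off})}; near-equal values of
#' this probability under swapped rate vectors are the root cause of
#' the model's near-unidentifiability without order constraints.
#'
#' @param p an [params()] object.
#' @return probability in (0, 1].
#' @export
loop_success_probability <- function(p) {
  stopifnot(inherits(p, "onoffseq_params"))
  p$lambdas[1L] / (p$lambdas[1L] + p$q_off)
}

#' Empirical distribution function of sampled times
#'
#' Thin wrapper around [stats::ecdf()] that also exposes the sorted
#' (t, F) pairs for export or plotting overlays of near-identical
#' inter-birth-time laws.
#'
#' @param samples numeric vector of times (non-empty).
#' @return the right-continuous step function, with the sorted support
#'   points and cumulative probabilities attached as attribute
#'   `"table"` (a data.frame with columns `t`, `F`).
#' @export
ecdf_times <- function(samples) {
  if (length(samples) < 1L) stop("need at least one sample")
  f <- stats::ecdf(samples)
  t_sorted <- sort(unique(samples))
  attr(f, "table") <- data.frame(t = t_sorted, F = f(t_sorted))
  f
}
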