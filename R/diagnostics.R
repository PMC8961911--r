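#' Kernel diagnostics for a model configuration
#'
#' Builds the Erlangization kernel at the requested settings and
#' reports three error measures: the worst row-sum deviation from 1,
#' the stage-doubling error (max-abs difference between the kernels at
#' `ell` and `2 ell`, an internal convergence estimate of order
#' `1/ell`), and, when the state space is small enough for a dense
#' reference, the max-abs difference from the uniformization matrix
#' exponential.
#'
#' @param p an [params()] object.
#' @param spec model specification (defaults to `p$spec`).
#' @param C truncation level.
#' @param delta observation lag.
#' @param ell Erlang stages.
#' @param oracle_max_D largest state count for which the dense
#'   matrix-exponential reference is computed.
#' @return a list with `row_sum_error`, `doubling_error`,
#'   `oracle_error` (`NA` if skipped), and the settings used.
#' @export
kernel_check <- function(p, spec = p$spec, C, delta = 1, ell = 2048L,
                         oracle_max_D = 200L) {
  gen <- assemble_generator(build_blocks(p, spec, C))
  k1 <- erlang_kernel(gen, delta, ell)
  k2 <- erlang_kernel(gen, delta, 2L * ell)
  oracle <- if (gen$state_space$D <= oracle_max_D)
    max(abs(k1$P - matrix_exponential_oracle(gen, delta))) else NA_real_
  list(row_sum_error = max(abs(rowSums(k1$P) - 1)),
       doubling_error = max(abs(k1$P - k2$P)),
       oracle_error = oracle,
       settings = list(C = C, D = gen$state_space$D, delta = delta,
                       ell = ell))
}
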