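#' Define an on/off-seq-L model family
#'
#' The on/off-seq-L process is a birth-death model of RNA transcription:
#' a birth requires `L` sequential exponential phases (rates
#' `lambda_1..lambda_L`) and can only be initiated while a promoter
#' on/off switch is in the on state (switching rates `q_on`, `q_off`);
#' every molecule dies independently at rate `mu`.  A model
#' specification fixes the structural choices of the family: the number
#' of phases, whether the switch is present, whether all phase rates
#' are tied to a single value, and which parameters are held fixed at
#' known values (typically `mu = 0` for a pure-birth analysis).
#'
#' The hidden phase process \eqn{X_t} lives on \eqn{E = \{0, 1, ..., L\}}
#' (state 0 = switch off, 1 = on / first phase, 2..L later phases); the
#' switchless seq-L variant drops state 0 together with `q_on`/`q_off`.
#'
#' @param L integer, number of sequential birth phases (>= 1).
#' @param has_switch logical, include the on/off switch?
#' @param tied_lambdas logical, constrain all phase rates to one value?
#' @param fixed named numeric vector of parameters held at known values,
#'   e.g. `c(mu = 0)`.  Fixed parameters are excluded from the free
#'   parameter count `k` used by the AIC.
#' @return an object of class `"onoffseq_spec"` with fields `L`,
#'   `has_switch`, `tied_lambdas`, `fixed`, the phase set `E` and the
#'   free-parameter count `k`.
#' @examples
#' model_spec(2)                      # on/off-seq-2, all parameters free
#' model_spec(2, fixed = c(mu = 0))   # pure-birth on/off-seq-2
#' model_spec(3, tied_lambdas = TRUE) # on/off-seq-3 with equal rates
#' model_spec(1, has_switch = FALSE)  # seq-1: constant-rate birth-death
#' @export
model_spec <- function(L, has_switch = TRUE, tied_lambdas = FALSE,
                       fixed = numeric(0)) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 1L)
    stop("L must be a single integer >= 1")
  fixed <- unlist(fixed)
  if (length(fixed) && is.null(names(fixed)))
    stop("'fixed' must be a named vector, e.g. c(mu = 0)")
  allowed <- c(if (has_switch) c("q_on", "q_off"),
               if (tied_lambdas) "lambda" else paste0("lambda", seq_len(L)),
               "mu")
  bad <- setdiff(names(fixed), allowed)
  if (length(bad))
    stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  E <- if (has_switch) 0:L else 1:L
  free <- setdiff(allowed, names(fixed))
  out <- list(L = L, has_switch = isTRUE(has_switch),
              tied_lambdas = isTRUE(tied_lambdas),
              fixed = fixed, E = E, free_names = free,
              k = length(free))
  class(out) <- "onoffseq_spec"
  out
}

#' @export
print.onoffseq_spec <- function(x, ...) {
  fam <- sprintf("%sseq-%d", if (x$has_switch) "on/off-" else "", x$L)
  cat(fam, "model:", x$k, "free parameter(s):",
      paste(x$free_names, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n")
  if (x$tied_lambdas) cat("  all phase rates tied\n")
  invisible(x)
}

#' Rate parameters of an on/off-seq-L process
#'
#' Bundles the rate vector
#' \eqn{\theta = (q_{on}, q_{off}, \lambda_1, ..., \lambda_L, \mu)} and
#' validates it against a model specification: all rates non-negative,
#' all phase rates strictly positive, switch rates present exactly when
#' the switch is, and values consistent with the specification's fixed
#' parameters and tied-rate flag.
#'
#' @param spec a [model_spec()].
#' @param q_on,q_off switch rates (off-to-on and on-to-off), per unit
#'   time; must be `NULL` when the specification has no switch.
#' @param lambdas numeric vector of the `L` phase-completion rates (a
#'   single value is recycled when the rates are tied).
#' @param mu per-molecule death rate, per unit time.
#' @return an object of class `"onoffseq_params"`.
#' @examples
#' sp <- model_spec(2, fixed = c(mu = 0))
#' params(sp, q_on = 0.1, q_off = 0.2, lambdas = c(2, 1), mu = 0)
#' @export
params <- function(spec, q_on = NULL, q_off = NULL, lambdas, mu = 0) {
  stopifnot(inherits(spec, "onoffseq_spec"))
  if (spec$has_switch) {
    if (is.null(q_on) || is.null(q_off))
      stop("q_on and q_off are required when the switch is present")
  } else {
    if (!is.null(q_on) || !is.null(q_off))
      stop("q_on/q_off must be absent for a switchless seq-L model")
    q_on <- q_off <- 0
  }
  lambdas <- as.numeric(lambdas)
  if (spec$tied_lambdas && length(lambdas) == 1L)
    lambdas <- rep(lambdas, spec$L)
  if (length(lambdas) != spec$L)
    stop("need ", spec$L, " phase rate(s), got ", length(lambdas))
  if (spec$tied_lambdas && length(unique(lambdas)) != 1L)
    stop("phase rates are tied in this specification but differ")
  th <- c(q_on = q_on, q_off = q_off, mu = mu)
  if (any(!is.finite(c(th, lambdas))) || any(c(th, lambdas) < 0))
    stop("all rates must be finite and non-negative")
  if (any(lambdas <= 0))
    stop("all phase rates lambda_i must be strictly positive")
  for (nm in names(spec$fixed)) {
    val <- switch(nm, q_on = q_on, q_off = q_off, mu = mu,
                  lambda = lambdas[1L],
                  lambdas[as.integer(sub("lambda", "", nm))])
    if (abs(val - spec$fixed[[nm]]) > 1e-12)
      stop("parameter ", nm, " is fixed at ", spec$fixed[[nm]],
           " by the model specification")
  }
  out <- list(q_on = q_on, q_off = q_off, lambdas = lambdas, mu = mu,
              spec = spec)
  class(out) <- "onoffseq_params"
  out
}

#' @export
print.onoffseq_params <- function(x, ...) {
  v <- theta_vector(x)
  cat(sprintf("%s parameters:\n", sprintf("%sseq-%d",
      if (x$spec$has_switch) "on/off-" else "", x$spec$L)))
  print(round(v, 6))
  invisible(x)
}

#' Flatten parameters to the named rate vector theta
#'
#' @param p an [params()] object.
#' @param free_only keep only the free (non-fixed) coordinates?
#' @return named numeric vector in the order
#'   `q_on, q_off, lambda_1..lambda_L (or lambda), mu`.
#' @export
theta_vector <- function(p, free_only = FALSE) {
  sp <- p$spec
  lam <- if (sp$tied_lambdas) c(lambda = p$lambdas[1L]) else
    stats::setNames(p$lambdas, paste0("lambda", seq_len(sp$L)))
  v <- c(if (sp$has_switch) c(q_on = p$q_on, q_off = p$q_off),
         lam, mu = p$mu)
  if (free_only) v[setdiff(names(v), names(sp$fixed))] else v
}

#' Build parameters from a named theta vector
#'
#' Inverse of [theta_vector()]: missing coordinates are taken from the
#' specification's fixed values.
#' @param spec a [model_spec()].
#' @param theta named numeric vector (free coordinates at least).
#' @return an `"onoffseq_params"` object.
#' @export
params_from_theta <- function(spec, theta) {
  full <- c(theta, spec$fixed[setdiff(names(spec$fixed), names(theta))])
  lam <- if (spec$tied_lambdas) rep(full[["lambda"]], spec$L) else
    full[paste0("lambda", seq_len(spec$L))]
  params(spec,
         q_on = if (spec$has_switch) full[["q_on"]],
         q_off = if (spec$has_switch) full[["q_off"]],
         lambdas = as.numeric(lam),
         mu = if ("mu" %in% names(full)) full[["mu"]] else 0)
}

#' State space of the truncated quasi birth-death process
#'
#' The bivariate chain (phase `x`, count `m`) with the count truncated
#' at level `C` has `D = |E| * (C + 1)` states.  The flat index is
#' level-major, `flat = m * |E| + rank(x)`, so the generator is block
#' tridiagonal with bandwidth `|E|`.
#'
#' @param spec a [model_spec()].
#' @param C population truncation level (>= 1).
#' @return a list with `L`, `C`, `E`, `D` and index helpers
#'   `flat(x, m)` / `unflat(i)` (both 1-based flat positions).
#' @export
state_space <- function(spec, C) {
  stopifnot(inherits(spec, "onoffseq_spec"))
  C <- as.integer(C)
  if (C < 1L) stop("truncation level C must be >= 1")
  E <- spec$E
  nE <- length(E)
  off <- E[1L]                      # 0 with switch, 1 without
  list(L = spec$L, C = C, E = E, D = nE * (C + 1L), n_phases = nE,
       flat = function(x, m) m * nE + (x - off) + 1L,
       unflat = function(i) {
         i0 <- i - 1L
         list(x = i0 %% nE + off, m = i0 %/% nE)
       })
}

#' Level blocks of the quasi birth-death generator
#'
#' Decomposes the generator of the truncated (phase, count) chain into
#' its level blocks: `within_level[[m+1]]` holds the phase transitions
#' that leave the count at `m` (switching and non-terminal phase
#' advances, diagonal chosen so each block has zero row sums in
#' isolation), `births[[m+1]]` the single birth transition (rate
#' `lambda_L` from phase L back to phase 1, raising the count by one;
#' absent at the truncation level `C`), and `deaths[[m]]` the diagonal
#' death block `m * mu * I` for `m = 1..C`.
#'
#' @param p an [params()] object.
#' @param spec the model specification (defaults to `p$spec`).
#' @param C truncation level.
#' @return a list of class `"qbd_blocks"` with fields `within_level`,
#'   `births`, `deaths` and the `state_space`.
#' @export
build_blocks <- function(p, spec = p$spec, C) {
  stopifnot(inherits(p, "onoffseq_params"))
  ss <- state_space(spec, C)
  nE <- ss$n_phases
  L <- spec$L
  lab <- as.character(spec$E)
  W <- matrix(0, nE, nE, dimnames = list(lab, lab))
  r <- function(x) x - spec$E[1L] + 1L   # phase -> row
  if (spec$has_switch) {
    W[r(0), r(1)] <- p$q_on
    W[r(1), r(0)] <- p$q_off
  }
  if (L >= 2L)
    for (i in 1:(L - 1L)) W[r(i), r(i + 1L)] <- p$lambdas[i]
  diag(W) <- diag(W) - rowSums(W)
  B <- matrix(0, nE, nE, dimnames = list(lab, lab))
  B[r(L), r(1)] <- p$lambdas[L]          # birth: phase L -> 1, count +1
  out <- list(
    within_level = rep(list(W), C + 1L),
    births = rep(list(B), C),
    deaths = lapply(seq_len(C), function(m) {
      D <- diag(m * p$mu, nE)
      dimnames(D) <- list(lab, lab)
      D
    }),
    state_space = ss)
  class(out) <- "qbd_blocks"
  out
}

#' Assemble the full block-tridiagonal generator
#'
#' Stacks the level blocks into the `D x D` rate matrix of the
#' truncated chain.  The diagonal blocks are the within-level blocks
#' with their diagonals re-adapted so every full row of `Q` sums to
#' zero (the adaptation depends on the level through the birth and
#' death rates); the level-`C` row has no birth block, so at (phase L,
#' count C) the process can only leave by a death.
#'
#' @param blocks a [build_blocks()] result.
#' @return an object of class `"qbd_generator"`: list with the dense
#'   matrix `Q` and the `state_space`.
#' @export
assemble_generator <- function(blocks) {
  stopifnot(inherits(blocks, "qbd_blocks"))
  ss <- blocks$state_space
  nE <- ss$n_phases
  C <- ss$C
  D <- ss$D
  dims <- vapply(c(blocks$within_level, blocks$births, blocks$deaths),
                 function(b) all(dim(b) == c(nE, nE)), logical(1))
  if (!all(dims)) stop("inconsistent block dimensions")
  Q <- matrix(0, D, D)
  idx <- function(m) (m * nE + 1L):((m + 1L) * nE)
  for (m in 0:C) {
    Q[idx(m), idx(m)] <- blocks$within_level[[m + 1L]]
    if (m < C) Q[idx(m), idx(m + 1L)] <- blocks$births[[m + 1L]]
    if (m > 0) Q[idx(m), idx(m - 1L)] <- blocks$deaths[[m]]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  out <- list(Q = Q, state_space = ss)
  class(out) <- "qbd_generator"
  out
}

#' Stationary distribution of the marginal phase chain
#'
#' The phase process \eqn{X_t} is an autonomous finite chain on `E`
#' (switching between off and on, sequential phase advances, and the
#' birth transition returning phase L to phase 1).  Its unique
#' stationary law is the model's initial phase distribution.  For
#' `L = 1` the birth transition is a self-loop of the phase and does
#' not enter the marginal generator.
#'
#' @param p an [params()] object.
#' @param spec the model specification (defaults to `p$spec`).
#' @return probability vector over `E` (named by phase).
#' @export
stationary_phase_distribution <- function(p, spec = p$spec) {
  stopifnot(inherits(p, "onoffseq_params"))
  E <- spec$E
  nE <- length(E)
  if (nE == 1L) return(stats::setNames(1, as.character(E)))
  if (spec$has_switch && (p$q_on <= 0 || p$q_off < 0))
    if (p$q_on <= 0)
      stop("q_on must be > 0 for a unique stationary phase distribution")
  QX <- matrix(0, nE, nE)
  r <- function(x) x - E[1L] + 1L
  L <- spec$L
  if (spec$has_switch) {
    QX[r(0), r(1)] <- p$q_on
    QX[r(1), r(0)] <- p$q_off
  }
  if (L >= 2L) {
    for (i in 1:(L - 1L)) QX[r(i), r(i + 1L)] <- p$lambdas[i]
    QX[r(L), r(1)] <- QX[r(L), r(1)] + p$lambdas[L]   # birth returns to 1
  }
  diag(QX) <- diag(QX) - rowSums(QX)
  # null-space solve: replace one balance equation by the normalization
  A <- t(QX)
  A[nE, ] <- 1
  b <- c(rep(0, nE - 1L), 1)
  pi_x <- tryCatch(solve(A, b), error = function(e)
    stop("phase chain is reducible or degenerate: ", conditionMessage(e)))
  if (any(pi_x < -1e-10))
    stop("phase chain is reducible or degenerate (negative solution)")
  pi_x <- pmax(pi_x, 0)
  pi_x <- pi_x / sum(pi_x)
  resid <- max(abs(pi_x %*% QX))
  if (resid > 1e-10)
    stop("stationary solve did not converge (residual ", resid, ")")
  stats::setNames(pi_x, as.character(E))
}
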