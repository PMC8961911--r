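#' Order constraints and box bound for likelihood maximization
#'
#' Interchanging the later phase rates \eqn{\lambda_2, ..., \lambda_L}
#' leaves the observable count process identically distributed, and
#' near-swaps of \eqn{\lambda_1} with another rate (compensated through
#' `q_off`) leave it nearly so.  Likelihood maximization for `L >= 2`
#' therefore requires an order constraint to pin a single branch.  The
#' constraint is a full chain over the phase-rate indices; the box
#' bound `b` defines the search domain `[0, b]` per coordinate, doubled
#' automatically when an estimate lands on the boundary.
#'
#' @param increasing integer vector: a permutation of `1:L` listing the
#'   phase-rate indices from smallest to largest.  For example `c(2, 1)`
#'   imposes \eqn{\lambda_2 \le \lambda_1} and `c(3, 2, 1)` imposes
#'   \eqn{\lambda_3 \le \lambda_2 \le \lambda_1}.  `NULL` means
#'   unconstrained.
#' @param b box upper bound (> 0) for every free coordinate.
#' @return an object of class `"constraint_set"`.
#' @export
constraint_set <- function(increasing = NULL, b = 10) {
  if (!is.null(increasing)) {
    increasing <- as.integer(increasing)
    if (anyDuplicated(increasing) || any(increasing < 1L))
      stop("'increasing' must be distinct positive phase-rate indices")
  }
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("box bound b must be a single positive number")
  structure(list(increasing = increasing, b = b),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  if (is.null(x$increasing)) cat("unconstrained")
  else cat(paste(sprintf("lambda%d", x$increasing), collapse = " <= "))
  cat(", box [0, ", x$b, "]\n", sep = "")
  invisible(x)
}

format_constraint <- function(cs) {
  if (is.null(cs$increasing)) "none" else
    paste(sprintf("l%d", cs$increasing), collapse = "<=")
}

# --- transform between the optimizer scale u and the named theta -----
#
# Free scalar coordinates are optimized on the log scale.  A chain
# lambda_{i1} <= ... <= lambda_{iJ} is reparameterized as
# lambda_{i1} = exp(u_1), lambda_{ij} = lambda_{i(j-1)} + exp(u_j),
# which turns the partial order into a plain box for L-BFGS-B.
make_transform <- function(spec, cs) {
  free <- spec$free_names
  lam_names <- grep("^lambda", free, value = TRUE)
  chain <- NULL
  if (!is.null(cs$increasing) && !spec$tied_lambdas) {
    if (!setequal(cs$increasing, seq_len(spec$L)))
      stop("constraint chain must order all ", spec$L, " phase rates")
    chain <- paste0("lambda", cs$increasing)
    if (!all(chain %in% free))
      stop("constrained phase rates must be free parameters")
  }
  scalar <- setdiff(free, if (is.null(chain)) character(0) else chain[-1L])
  list(
    n_par = length(free),
    # start 'theta' (named, natural scale, order-feasible) -> u
    to_u = function(theta) {
      u <- log(theta[scalar])
      if (!is.null(chain) && length(chain) > 1L) {
        inc <- diff(theta[chain])
        if (any(inc < 0)) stop("start violates the order constraint")
        u <- c(u, stats::setNames(log(pmax(inc, 1e-12)), chain[-1L]))
      }
      u[c(scalar, if (!is.null(chain)) chain[-1L])]
    },
    to_theta = function(u) {
      theta <- exp(u[scalar])
      if (!is.null(chain)) {
        lam <- cumsum(c(theta[chain[1L]], exp(u[chain[-1L]])))
        theta[chain] <- lam
      }
      theta[free]
    })
}

# Data-driven start: crude rate estimates from the observed increments.
# Births per unit time from the positive increments give 1/E[T]; the
# loop correction and the phase passage are each allotted half of E[T]
# (equal phase rates); the death rate is decrements per molecule-time.
# Deliberately rough -- it only needs to land in the basin where the
# switch is slower than the phases, away from the degenerate
# always-on corner of the likelihood.
moment_start <- function(data, spec, b) {
  free <- spec$free_names
  d <- unlist(lapply(data$series, function(s) diff(s$counts)))
  tt <- sum(vapply(data$series, function(s) length(s$counts) - 1L,
                   integer(1))) * data$delta
  birth_rate <- sum(pmax(d, 0)) / tt
  if (!is.finite(birth_rate) || birth_rate <= 0) birth_rate <- 0.01
  ET <- 1 / birth_rate
  mol_time <- sum(vapply(data$series, function(s)
    sum(s$counts[-length(s$counts)]), integer(1))) * data$delta
  mu0 <- if (mol_time > 0) sum(pmax(-d, 0)) / mol_time else 0
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 1e-3
  lam <- if (spec$has_switch) 2 * spec$L / ET else spec$L / ET
  th <- c(q_on = 2 / ET, q_off = lam, lambda = lam, mu = mu0,
          stats::setNames(rep(lam, spec$L), paste0("lambda", seq_len(spec$L))))
  pmin(pmax(th[free], b * 1e-8), b * 0.999)
}

draw_start <- function(spec, cs, b) {
  free <- spec$free_names
  th <- stats::setNames(exp(stats::runif(length(free),
                                         log(b * 1e-3), log(b))), free)
  if (!is.null(cs$increasing) && !spec$tied_lambdas) {
    chain <- paste0("lambda", cs$increasing)
    th[chain] <- sort(th[chain])        # respect the chosen branch
  }
  th
}

#' Constrained maximum-likelihood fit
#'
#' Maximizes the total log-likelihood over the free parameters subject
#' to the box and order constraints, by multi-start L-BFGS-B on a
#' transformed scale (log coordinates; order chains as cumulative
#' positive increments).  The start pool holds a data-driven
#' moment-based point plus `starts` points drawn log-uniformly over
#' `[b * 1e-3, b]` (sorted to satisfy the chain); each candidate is
#' screened with a single likelihood evaluation and full optimization
#' runs from the best `refine` of them.  If the best
#' estimate ends within `1e-6 * b` of the box bound, the box is
#' doubled and the fit restarted from the current estimate (at most
#' three doublings) -- an estimate on the boundary signals that the
#' domain, not the data, capped it.
#'
#' @param data an `"observation_set"`.
#' @param spec a [model_spec()].
#' @param constraints a [constraint_set()]; for `L >= 2` with untied
#'   free phase rates a chain is required unless
#'   `allow_unconstrained = TRUE` (the unconstrained likelihood has
#'   symmetric maxima and the returned branch is then arbitrary).
#' @param C truncation level, or `"auto"` for `max(2 * max count, 20)`.
#' @param ell Erlang stages (power of two).
#' @param starts number of random start candidates in the pool.
#' @param refine number of screened candidates optimized to
#'   convergence.
#' @param seed optional seed for the start draws.
#' @param maxit,factr L-BFGS-B control.
#' @param allow_unconstrained permit an unconstrained fit for `L >= 2`.
#' @return an object of class `"onoffseq_fit"`: the estimate
#'   (`params`, and named vector `theta`), `loglik`, `aic`, `k`,
#'   `constraints`, `boundary_hit`, `enlargements`, `starts`,
#'   `converged`, `n_eval` and the numeric `settings`.
#' @export
fit_mle <- function(data, spec, constraints = constraint_set(),
                    C = "auto", ell = 2048L, starts = 5L, refine = 2L,
                    seed = NULL, maxit = 500L, factr = 1e7,
                    allow_unconstrained = FALSE) {
  stopifnot(inherits(data, "observation_set"),
            inherits(spec, "onoffseq_spec"),
            inherits(constraints, "constraint_set"))
  n_free_lam <- sum(grepl("^lambda", spec$free_names))
  if (is.null(constraints$increasing) && !spec$tied_lambdas &&
      n_free_lam >= 2L && !allow_unconstrained)
    stop("the model with L >= 2 untied phase rates is not identifiable ",
         "without an order constraint; supply one or set ",
         "allow_unconstrained = TRUE")
  data_max <- max(vapply(data$series, function(s) max(s$counts),
                         integer(1)))
  if (identical(C, "auto")) C <- max(2L * data_max, 20L)
  if (C <= data_max)
    stop("truncation C = ", C, " must exceed the largest observed count ",
         data_max)
  if (!is.null(seed)) set.seed(seed)

  n_eval <- 0L
  objective_for <- function(tr) function(u) {
    th <- tr$to_theta(u)
    n_eval <<- n_eval + 1L
    p <- params_from_theta(spec, th)
    ll <- total_loglik(p, spec, data, C = C, ell = ell)$value
    if (!is.finite(ll)) 1e15 else -ll
  }

  run_from <- function(theta0, b) {
    tr <- make_transform(spec, constraints)
    u0 <- tr$to_u(theta0)
    lo <- rep(log(b * 1e-9), length(u0))
    hi <- rep(log(b), length(u0))
    res <- stats::optim(pmin(pmax(u0, lo), hi), objective_for(tr),
                        method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = maxit, factr = factr))
    list(theta = tr$to_theta(res$par), value = -res$value,
         converged = res$convergence == 0)
  }

  b <- constraints$b
  # Start pool: a data-driven moment start plus 'starts' log-uniform
  # draws.  Each candidate is screened with a single likelihood
  # evaluation and full local optimization is run from the best
  # 'refine' candidates; the screened likelihood separates the
  # basin of the truth-like optimum from the degenerate corners far
  # more cheaply than optimizing every start to convergence.
  pool <- c(list(moment_start(data, spec, b)),
            lapply(seq_len(starts), function(s)
              draw_start(spec, constraints, b)))
  if (!is.null(constraints$increasing) && !spec$tied_lambdas) {
    chain <- paste0("lambda", constraints$increasing)
    pool <- lapply(pool, function(th) {
      th[chain] <- sort(th[chain]); th })
  }
  tr0 <- make_transform(spec, constraints)
  obj0 <- objective_for(tr0)
  screened <- vapply(pool, function(th)
    tryCatch(obj0(tr0$to_u(th)), error = function(e) Inf), numeric(1))
  # the moment start is always refined (it tracks the data scale); the
  # random candidates compete for the remaining 'refine' slots
  top_random <- 1L + order(screened[-1L])[
    seq_len(min(refine, sum(is.finite(screened[-1L]))))]
  top <- unique(c(if (is.finite(screened[1L])) 1L, top_random))
  best <- NULL
  for (s in top) {
    fit_s <- tryCatch(run_from(pool[[s]], b), error = function(e) NULL)
    if (!is.null(fit_s) &&
        (is.null(best) || fit_s$value > best$value)) best <- fit_s
  }
  if (is.null(best))
    stop("all ", length(top), " optimizer starts failed")

  # Edge-split polish: the order-constraint edge (adjacent phase rates
  # equal, with a compensating q_off) is a recurrent local maximum of
  # this likelihood.  If the fit sits near that edge, probe once from
  # a spread perturbation and keep the better of the two.
  if (!is.null(constraints$increasing) && !spec$tied_lambdas) {
    chain <- paste0("lambda", constraints$increasing)
    lam_hat <- best$theta[chain]
    if (length(lam_hat) >= 2L &&
        any(lam_hat[-1L] / lam_hat[-length(lam_hat)] < 1.25)) {
      spread <- best$theta
      spread[chain[1L]] <- lam_hat[1L] * 0.5
      spread[chain[length(chain)]] <- lam_hat[length(chain)] * 2
      alt <- tryCatch(run_from(spread, b), error = function(e) NULL)
      if (!is.null(alt) && alt$value > best$value) best <- alt
    }
  }

  enlargements <- 0L
  boundary_hit <- FALSE
  while (any(best$theta >= b * (1 - 1e-6)) && enlargements < 3L) {
    boundary_hit <- TRUE
    b <- 2 * b
    enlargements <- enlargements + 1L
    nxt <- tryCatch(run_from(best$theta, b), error = function(e) NULL)
    if (is.null(nxt)) break
    if (nxt$value >= best$value) best <- nxt
  }
  if (any(best$theta >= b * (1 - 1e-6))) boundary_hit <- TRUE

  p_hat <- params_from_theta(spec, best$theta)
  k <- spec$k
  out <- list(params = p_hat, theta = best$theta, loglik = best$value,
              aic = 2 * k - 2 * best$value, k = k,
              constraints = constraints, boundary_hit = boundary_hit,
              enlargements = enlargements, b_final = b,
              starts = starts, converged = best$converged,
              n_eval = n_eval,
              settings = list(C = C, ell = ell, delta = data$delta))
  class(out) <- "onoffseq_fit"
  out
}

#' @export
print.onoffseq_fit <- function(x, ...) {
  cat(sprintf("%sseq-%d fit (%s):\n",
              if (x$params$spec$has_switch) "on/off-" else "",
              x$params$spec$L, format_constraint(x$constraints)))
  print(round(x$theta, 4))
  cat(sprintf("  log L = %.1f   AIC = %.1f   (k = %d, C = %d, ell = %d)\n",
              x$loglik, x$aic, x$k, x$settings$C, x$settings$ell))
  if (x$boundary_hit)
    cat("  note: boundary hit;", x$enlargements,
        "domain doubling(s), final b =", x$b_final, "\n")
  invisible(x)
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2k - 2 log L` with `k` the number of free parameters of the
#' model specification (fixed parameters excluded).  `exclude` drops
#' further named parameters from `k`, which is useful when mirroring
#' report conventions that do not count a nuisance rate such as `mu`.
#'
#' @param fit an `"onoffseq_fit"`.
#' @param exclude character vector of parameter names to drop from `k`.
#' @return the AIC value.
#' @export
aic <- function(fit, exclude = NULL) {
  stopifnot(inherits(fit, "onoffseq_fit"))
  k <- fit$k - length(intersect(exclude, names(fit$theta)))
  2 * k - 2 * fit$loglik
}

#' Default six-model candidate battery
#'
#' The seq-1/2/3 and on/off-seq-1/2/3 variants with a free death rate,
#' under the identifiability chains \eqn{\lambda_1 \ge \lambda_2} and
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}.
#'
#' @param b box bound shared by all candidates.
#' @return named list of `list(spec, constraints)` candidates.
#' @export
default_candidates <- function(b = 10) {
  chain <- function(L) switch(L, NULL, c(2L, 1L), c(3L, 2L, 1L))
  out <- list()
  for (sw in c(FALSE, TRUE)) for (L in 1:3) {
    nm <- sprintf("%sseq-%d", if (sw) "on/off-" else "", L)
    out[[nm]] <- list(spec = model_spec(L, has_switch = sw),
                      constraints = constraint_set(chain(L), b = b))
  }
  out
}

#' AIC model selection over candidate models
#'
#' Fits every candidate and ranks them by AIC (ascending; ties broken
#' by fewer free parameters).  A candidate whose fit fails is reported
#' with `NA` values rather than aborting the selection.
#'
#' @param data an `"observation_set"`.
#' @param candidates named list of `list(spec, constraints)`; default
#'   [default_candidates()].
#' @param ... passed to [fit_mle()] (e.g. `C`, `ell`, `starts`, `seed`).
#' @return an object of class `"onoffseq_selection"`: list with the
#'   ranked `table` (data.frame: model, constraint, k, loglik, AIC) and
#'   the `fits`.
#' @export
model_select <- function(data, candidates = default_candidates(), ...) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(cand)
    tryCatch(fit_mle(data, cand$spec, cand$constraints, ...),
             error = function(e) structure(list(error =
               conditionMessage(e)), class = "onoffseq_fit_failure")))
  tab <- data.frame(
    model = names(candidates),
    constraint = vapply(candidates, function(cand)
      format_constraint(cand$constraints), character(1)),
    k = vapply(fits, function(f)
      if (inherits(f, "onoffseq_fit")) f$k else NA_integer_, integer(1)),
    loglik = vapply(fits, function(f)
      if (inherits(f, "onoffseq_fit")) f$loglik else NA_real_, numeric(1)),
    AIC = vapply(fits, function(f)
      if (inherits(f, "onoffseq_fit")) f$aic else NA_real_, numeric(1)),
    row.names = NULL)
  ord <- order(tab$AIC, tab$k, na.last = TRUE)
  structure(list(table = tab[ord, ], fits = fits[ord]),
            class = "onoffseq_selection")
}

#' @export
print.onoffseq_selection <- function(x, ...) {
  tab <- x$table
  tab$loglik <- sprintf("%.1f", tab$loglik)
  tab$AIC <- sprintf("%.1f", tab$AIC)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Replicated parameter-recovery study
#'
#' Simulates `B` independent datasets from known parameters, fits each
#' one, and summarizes the estimates per coordinate (sample mean and
#' SD), reproducing the design of simulation-based accuracy studies.
#' Failed replicates are excluded from the summary and counted.
#'
#' @param true_params the generating [params()] object.
#' @param spec_fit model specification used for fitting (defaults to
#'   the generating one).
#' @param constraints a [constraint_set()] for the fits.
#' @param n lags per series; `N` series per dataset; `B` replicates.
#' @param delta observation lag; `m0` initial count.
#' @param x0 initial phase of the simulated cells (`NULL`: stationary;
#'   `1`: switch on -- see [sample_dataset()]).
#' @param seed root seed; replicate `i` derives its simulation and
#'   start-draw seeds from it.
#' @param ... further arguments to [fit_mle()].
#' @return an object of class `"onoffseq_recovery"`: list with the
#'   `B x k` matrix `estimates`, the `summary` data.frame (mean, sd),
#'   and `n_failed`.
#' @export
recovery_study <- function(true_params, spec_fit = true_params$spec,
                           constraints = constraint_set(), n, N, B,
                           delta = 1, m0 = 0L, x0 = NULL, seed = 1L,
                           ...) {
  est <- vector("list", B)
  failed <- 0L
  for (i in seq_len(B)) {
    rep_seed <- series_seed(seed, 7919L * i)
    dat <- sample_dataset(true_params, N = N, lengths = n,
                          delta = delta, m0 = m0, seed = rep_seed,
                          x0 = x0)
    fit <- tryCatch(fit_mle(dat, spec_fit, constraints,
                            seed = rep_seed + 1, ...),
                    error = function(e) NULL)
    if (is.null(fit)) failed <- failed + 1L else est[[i]] <- fit$theta
  }
  est <- do.call(rbind, est)
  if (is.null(est)) stop("every replicate failed to fit")
  structure(list(
    estimates = est,
    summary = data.frame(parameter = colnames(est),
                         mean = colMeans(est),
                         sd = apply(est, 2, stats::sd),
                         row.names = NULL),
    n_failed = failed, B = B,
    design = list(n = n, N = N, delta = delta, m0 = m0,
                  x0 = if (is.null(x0)) "stationary" else x0,
                  seed = seed)),
    class = "onoffseq_recovery")
}

#' @export
print.onoffseq_recovery <- function(x, ...) {
  cat(sprintf("recovery study: B = %d replicates (%d failed)\n",
              x$B, x$n_failed))
  s <- x$summary
  s$mean <- sprintf("%.4f", s$mean)
  s$sd <- sprintf("%.4f", s$sd)
  print(s, row.names = FALSE)
  invisible(x)
}
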