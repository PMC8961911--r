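test_that("AIC arithmetic and exclusion of nuisance parameters", {
  fake <- structure(list(loglik = -3569.9, k = 1,
                         theta = c(lambda1 = 0.0144, mu = 0.01)),
                    class = "onoffseq_fit")
  expect_equal(aic(fake), 7141.8)
  fake0 <- structure(list(loglik = -10, k = 0, theta = c(mu = 1)),
                     class = "onoffseq_fit")
  expect_equal(aic(fake0), 20)
  fake2 <- structure(list(loglik = -3569.9, k = 2,
                          theta = c(lambda1 = 0.0144, mu = 0.01)),
                     class = "onoffseq_fit")
  expect_equal(aic(fake2), aic(fake) + 2)        # one extra parameter
  expect_equal(aic(fake2, exclude = "mu"), aic(fake))
})

test_that("constraint sets validate and unconstrained L >= 2 is refused", {
  expect_error(constraint_set(c(1, 1)), "distinct")
  expect_error(constraint_set(b = -1), "positive")
  p <- theta_bd_params()
  dat <- sample_dataset(p, N = 3, lengths = 10, seed = 1)
  expect_error(fit_mle(dat, p$spec, constraint_set(NULL, 10)),
               "order constraint")
  expect_error(fit_mle(dat, p$spec, constraint_set(c(2, 1), 10), C = 2),
               "exceed")
})

test_that("fitting recovers parameters, honors constraints and is
           invariant to series order", {
  p <- theta_bd_params()
  dat <- sample_dataset(p, N = 80, lengths = 60, seed = 21)
  cs <- constraint_set(c(2, 1), b = 10)
  fit <- fit_mle(dat, p$spec, cs, seed = 22, starts = 3)
  expect_true(fit$converged)
  expect_gte(fit$theta[["lambda1"]], fit$theta[["lambda2"]])
  expect_true(all(fit$theta > 0))
  # estimates land in a loose neighborhood of the truth at this n, N
  expect_lt(abs(fit$theta[["mu"]] - 0.3), 0.1)
  expect_lt(abs(fit$theta[["q_on"]] - 0.1), 0.08)
  # AIC self-consistency: recomputing the likelihood at theta-hat
  ll <- total_loglik(fit$params, data = dat, C = fit$settings$C)$value
  expect_equal(ll, fit$loglik, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  # permuting the series leaves the fit unchanged (same start seed)
  perm <- structure(list(series = rev(dat$series), delta = dat$delta),
                    class = "observation_set")
  fit_p <- fit_mle(perm, p$spec, cs, seed = 22, starts = 3)
  expect_equal(fit_p$theta, fit$theta, tolerance = 1e-4)
})

test_that("a too-small box is detected and enlarged until the optimum
           fits", {
  sp <- model_spec(3, tied_lambdas = TRUE)
  p <- params(sp, q_on = 0.25, q_off = 1, lambdas = 10, mu = 2)
  dat <- sample_dataset(p, N = 60, lengths = 60, seed = 31)
  fit <- fit_mle(dat, sp, constraint_set(NULL, b = 2), seed = 32,
                 starts = 3)
  expect_true(fit$boundary_hit)
  expect_gte(fit$enlargements, 1)
  expect_lt(abs(fit$theta[["lambda"]] - 10) / 10, 0.2)
  # from b = 1 the three permitted doublings reach only b = 8, so the
  # estimate is still reported as boundary-capped
  fit1 <- fit_mle(dat, sp, constraint_set(NULL, b = 1), seed = 32,
                  starts = 3)
  expect_true(fit1$boundary_hit)
  expect_equal(fit1$enlargements, 3)
  expect_equal(fit1$b_final, 8)
})

test_that("model selection ranks a single candidate first and reports
           failures gracefully", {
  p <- theta_bd_params()
  dat <- sample_dataset(p, N = 30, lengths = 30, seed = 41)
  cand <- list("on/off-seq-2" = list(
    spec = p$spec, constraints = constraint_set(c(2, 1), 10)))
  sel <- model_select(dat, cand, seed = 42, starts = 2)
  expect_equal(nrow(sel$table), 1)
  expect_equal(sel$table$model, "on/off-seq-2")
  expect_equal(sel$table$k, 5)
})

test_that("recovery study aggregates replicate estimates", {
  sp <- model_spec(1, fixed = c(mu = 0))
  p <- params(sp, q_on = 0.5, q_off = 0.5, lambdas = 1, mu = 0)
  rec <- recovery_study(p, sp, constraint_set(NULL, 10), n = 40, N = 25,
                        B = 2, seed = 51, starts = 2)
  expect_equal(dim(rec$estimates), c(2, 3))
  expect_equal(rec$summary$parameter, c("q_on", "q_off", "lambda1"))
  expect_equal(rec$n_failed, 0)
})
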