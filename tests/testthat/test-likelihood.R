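test_that("initial phase weights are the stationary law, whatever m0", {
  p <- params(model_spec(1), q_on = 0.1, q_off = 0.2, lambdas = 1)
  expect_equal(unname(initial_phase_weights(p, m0 = 0)), c(2, 1) / 3)
  expect_equal(initial_phase_weights(p, m0 = 17),
               initial_phase_weights(p, m0 = 0))
  expect_equal(sum(initial_phase_weights(theta_bd_params(), m0 = 3)), 1)
})

test_that("forward recursion equals brute-force path enumeration", {
  set.seed(701)
  for (i in 1:12) {
    p <- random_params()
    C <- 6L
    ker <- erlang_kernel(assemble_generator(build_blocks(p, C = C)),
                         1, 256L)
    n <- sample(0:3, 1)
    counts <- pmax(0, pmin(cumsum(c(sample(0:2, 1),
                                    sample(-1:2, n, TRUE))), C))
    s <- make_series(counts)
    expect_equal(series_loglik(ker, p, series = s),
                 brute_force_loglik(ker, p, series = s),
                 tolerance = 1e-10)
  }
})

test_that("degenerate series and impossible transitions are handled", {
  p <- theta2_params()                   # mu = 0: deaths impossible
  ker <- erlang_kernel(assemble_generator(build_blocks(p, C = 10)),
                       1, 256L)
  expect_equal(series_loglik(ker, p, series = make_series(4)), 0)
  expect_identical(series_loglik(ker, p, series = make_series(c(3, 2))),
                   -Inf)
  expect_error(series_loglik(ker, p, series = make_series(c(0, 11))),
               "enlarge")
  expect_error(series_loglik(ker, p,
                             series = make_series(c(0, 1), delta = 2)),
               "lag")
})

test_that("dataset likelihood is additive over independent series", {
  p <- theta_bd_params()
  set.seed(702)
  dat <- sample_dataset(p, N = 1, lengths = 20, seed = 3)
  ll1 <- total_loglik(p, data = dat, C = 20)
  ker <- erlang_kernel(assemble_generator(build_blocks(p, C = 20)),
                       1, 2048L)
  expect_equal(ll1$value,
               series_loglik(ker, p, series = dat$series[[1]]))
  dup <- structure(list(series = rep(dat$series, 2), delta = 1),
                   class = "observation_set")
  expect_equal(total_loglik(p, data = dup, C = 20)$value, 2 * ll1$value)
  mixed <- sample_dataset(p, N = 2, lengths = c(50, 100), seed = 4)
  llm <- total_loglik(p, data = mixed, C = 20)
  expect_equal(llm$value, sum(llm$per_series))
  expect_length(llm$per_series, 2)
})

test_that("longer series are never more probable than their prefixes", {
  p <- theta_bd_params()
  set.seed(703)
  s_full <- sample_series(p, n = 30)
  ker <- erlang_kernel(assemble_generator(build_blocks(p, C = 20)),
                       1, 2048L)
  ll <- vapply(c(5, 15, 30), function(n)
    series_loglik(ker, p, series = make_series(s_full$counts[1:(n + 1)])),
    numeric(1))
  expect_true(all(diff(ll) <= 0))
})

test_that("pure-birth increment evaluation equals the full-kernel route", {
  p <- theta2_params()
  set.seed(704)
  for (i in 1:4) {
    dat <- sample_dataset(p, N = 4, lengths = 40, seed = 100 + i)
    fast <- total_loglik(p, data = dat, C = 100)$value
    ker <- erlang_kernel(assemble_generator(build_blocks(p, C = 100)),
                         1, 2048L)
    full <- sum(vapply(dat$series, function(s)
      series_loglik(ker, p, series = s), numeric(1)))
    expect_equal(fast, full, tolerance = 1e-10)
  }
})

test_that("the likelihood prefers the truth over a perturbed model", {
  p <- theta_bd_params()
  p_wrong <- params(p$spec, q_on = 0.1, q_off = 0.2,
                    lambdas = c(3, 1), mu = 0.3)   # lambda_1 x 1.5
  set.seed(705)
  better <- 0L
  for (i in 1:20) {
    dat <- sample_dataset(p, N = 60, lengths = 50, seed = 7000 + i)
    better <- better +
      (total_loglik(p, data = dat, C = 20)$value >
         total_loglik(p_wrong, data = dat, C = 20)$value)
  }
  expect_gte(better, 15)
})
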