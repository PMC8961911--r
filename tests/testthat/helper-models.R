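# Shared fixtures: parameter vectors used throughout the numerical
# study, and small helpers for building random model instances.

# on/off-seq-2, pure birth: the two near-indistinguishable vectors
theta1_params <- function() {
  sp <- model_spec(2, fixed = c(mu = 0))
  params(sp, q_on = 0.1, q_off = 0.1, lambdas = c(1, 2), mu = 0)
}
theta2_params <- function() {
  sp <- model_spec(2, fixed = c(mu = 0))
  params(sp, q_on = 0.1, q_off = 0.2, lambdas = c(2, 1), mu = 0)
}
# on/off-seq-2 with deaths (n/N influence and model-selection designs)
theta_bd_params <- function() {
  params(model_spec(2), q_on = 0.1, q_off = 0.2, lambdas = c(2, 1),
         mu = 0.3)
}

random_params <- function(L = sample(1:3, 1), mu_max = 0.5) {
  sp <- model_spec(L)
  params(sp, q_on = stats::runif(1, 0.05, 1),
         q_off = stats::runif(1, 0.05, 1),
         lambdas = stats::runif(L, 0.5, 3),
         mu = stats::runif(1, 0, mu_max))
}

# generator object over an arbitrary rate matrix (for closed-form
# kernel checks on chains that are not of the birth-phase family)
raw_generator <- function(Q) {
  ss <- state_space(model_spec(1, has_switch = FALSE), nrow(Q) - 1L)
  structure(list(Q = Q, state_space = ss), class = "qbd_generator")
}

make_series <- function(counts, delta = 1, id = "s1") {
  structure(list(counts = as.integer(counts), delta = delta,
                 series_id = id), class = "count_series")
}
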