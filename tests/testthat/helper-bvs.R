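# Sampler fixtures and independent MH-ratio oracles shared by the unit and
# acceptance tests.

make_bvs_instance <- function(n = 30, P = 6, seed = 11,
                              accuracy = test_accuracy(0.8, 0.95)) {
  set.seed(seed)
  X <- rexp(n, 0.12)
  panels <- simulate_self_reports(X, c(2, 4, 6, 8), accuracy)
  Z <- standardize_covariates(matrix(rnorm(n * P), n, P))
  bvs_data(panels, Z, accuracy)
}

random_state <- function(data, hyper, seed) {
  set.seed(seed)
  P <- ncol(data$Z)
  gamma <- as.integer(runif(P) < 0.4)
  if (all(gamma == 0)) gamma[1] <- 1L
  beta <- ifelse(gamma == 1, rnorm(P, sd = 0.8), 0)
  lp <- as.vector(data$Z %*% beta)
  pr <- srbvs:::profile_theta_h(exp(lp), data$obs)
  structure(list(gamma = gamma, beta = beta,
                 omega = runif(1, 0.05, 0.9), theta = pr$theta,
                 eta = pr$eta, loglik = pr$loglik, lp = lp,
                 K = sum(gamma)), class = "bvs_state")
}

# independent full log-target ratio for a flip proposal: likelihood x slab
# prior x Bernoulli(omega) prior, with the slab proposal density for the
# entering coefficient; everything recomputed from scratch
flip_delta_oracle <- function(state, fm, data, hyper) {
  gamma_new <- state$gamma
  beta_new <- state$beta
  gamma_new[fm$p] <- fm$proposal$gamma_p
  beta_new[fm$p] <- fm$proposal$beta_p
  log_joint <- function(gamma, beta, theta) {
    ll <- as.numeric(log_likelihood(theta, beta, data$Z, data$obs))
    slab <- sum(dnorm(beta[gamma == 1], 0, hyper$b, log = TRUE))
    K <- sum(gamma)
    ll + slab + K * log(state$omega) +
      (length(gamma) - K) * log(1 - state$omega)
  }
  turning_on <- fm$proposal$gamma_p == 1
  log_q_fwd <- if (turning_on)
    dnorm(fm$proposal$beta_p, 0, hyper$b, log = TRUE) else 0
  log_q_rev <- if (turning_on) 0 else
    dnorm(state$beta[fm$p], 0, hyper$b, log = TRUE)
  log_joint(gamma_new, beta_new, fm$proposal$theta) -
    log_joint(state$gamma, state$beta, state$theta) -
    log_q_fwd + log_q_rev
}

refine_delta_oracle <- function(state, rm, p, data, hyper) {
  beta_new <- state$beta
  beta_new[p] <- rm$proposal$beta_p
  ll_new <- as.numeric(log_likelihood(rm$proposal$theta, beta_new, data$Z,
                                      data$obs))
  ll_old <- as.numeric(log_likelihood(state$theta, state$beta, data$Z,
                                      data$obs))
  # symmetric random-walk proposal cancels; only the slab prior moves
  (ll_new + dnorm(beta_new[p], 0, hyper$b, log = TRUE)) -
    (ll_old + dnorm(state$beta[p], 0, hyper$b, log = TRUE))
}

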