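test_that("initialization profiles theta at beta = 0 and draws omega", {
  counts <- c(4, 6, 3, 2, 5)
  panels <- perfect_panels(rep(1:5, times = counts))
  Z <- standardize_covariates(matrix(rnorm(20 * 4), 20, 4))
  data <- bvs_data(panels, Z, test_accuracy(1, 1))
  hyper <- bvs_hyperparameters(n_iter = 10, burn_in = 2)
  set.seed(3)
  st <- initialize_state(data, hyper)
  expect_equal(st$theta, counts / 20, tolerance = 1e-6)
  expect_identical(st$gamma, integer(4))
  expect_identical(st$beta, numeric(4))
  set.seed(3)
  st2 <- initialize_state(data, hyper)
  expect_identical(st, st2)

  # omega is a Beta(w1, w2) draw
  set.seed(9)
  oms <- replicate(4000, initialize_state(data, hyper)$omega)
  mu <- 5 / 105
  se <- sqrt(mu * (1 - mu) / (5 + 100 + 1)) / sqrt(4000)
  expect_lt(abs(mean(oms) - mu), 3 * se)
})

test_that("flip move delta matches the independent MH-ratio oracle", {
  data <- make_bvs_instance()
  hyper <- bvs_hyperparameters(n_iter = 10, burn_in = 2)
  for (s in 1:100) {
    state <- random_state(data, hyper, seed = 1000 + s)
    fm <- flip_move(state, data, hyper)
    expect_lt(abs(fm$delta - flip_delta_oracle(state, fm, data, hyper)),
              1e-12)
    # point-mass branch: a turn-off proposal has coefficient exactly 0
    if (fm$proposal$gamma_p == 0) expect_identical(fm$proposal$beta_p, 0)
  }
})

test_that("flip prior-odds term vanishes at omega = 0.5", {
  data <- make_bvs_instance(seed = 21)
  hyper <- bvs_hyperparameters(n_iter = 10, burn_in = 2)
  state <- random_state(data, hyper, seed = 4)
  state$omega <- 0.5
  fm <- flip_move(state, data, hyper)
  expect_equal(fm$delta, fm$proposal$loglik - state$loglik,
               tolerance = 1e-12)
})

test_that("refine move delta matches the MH-ratio oracle", {
  data <- make_bvs_instance(seed = 31)
  hyper <- bvs_hyperparameters(n_iter = 10, burn_in = 2)
  for (s in 1:100) {
    state <- random_state(data, hyper, seed = 2000 + s)
    p <- which(state$gamma == 1)[1]
    rm_ <- refine_move(state, data, hyper, p)
    expect_lt(abs(rm_$delta - refine_delta_oracle(state, rm_, p, data,
                                                  hyper)),
              1e-12)
  }
  # contract violation on an excluded covariate
  state <- random_state(data, hyper, seed = 3)
  q <- which(state$gamma == 0)[1]
  expect_error(refine_move(state, data, hyper, q), "excluded covariate")
})

test_that("larger coefficient magnitude at equal likelihood is penalized", {
  # the slab-prior term makes delta negative when |beta*| > |beta| and the
  # likelihood part is held fixed
  b <- 1
  delta_prior <- function(b_old, b_new) (b_old^2 - b_new^2) / (2 * b^2)
  expect_lt(delta_prior(0.5, 1.2), 0)
  expect_gt(delta_prior(1.2, 0.5), 0)
})

test_that("gibbs omega draws from the conjugate Beta posterior", {
  hyper <- bvs_hyperparameters(n_iter = 10, burn_in = 2)
  state <- list(K = 0L)
  set.seed(8)
  draws <- replicate(20000, gibbs_omega(state, hyper, P = 100))
  a <- 5; bb <- 200
  mu <- a / (a + bb)
  v <- a * bb / ((a + bb)^2 * (a + bb + 1))
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / 20000))
  expect_lt(abs(var(draws) - v) / v, 0.05)

  # boundary case K = P
  state$K <- 100L
  set.seed(9)
  d2 <- replicate(20000, gibbs_omega(state, hyper, P = 100))
  mu2 <- 105 / 205
  expect_lt(abs(mean(d2) - mu2), 0.01)
})

test_that("chain keeps the spike exact and the cached loglik consistent", {
  data <- make_bvs_instance(n = 25, P = 5, seed = 41)
  hyper <- bvs_hyperparameters(b = 1, n_iter = 40, burn_in = 5)
  set.seed(12)
  state <- initialize_state(data, hyper)
  for (it in 1:40) {
    fm <- flip_move(state, data, hyper)
    state <- fm$state
    for (p in which(state$gamma == 1L)) {
      if (runif(1) < hyper$p_main) state <- refine_move(state, data,
                                                        hyper, p)$state
    }
    state$omega <- gibbs_omega(state, hyper, ncol(data$Z))
    expect_true(all(state$beta[state$gamma == 0L] == 0))
    expect_lt(abs(state$loglik -
                  as.numeric(log_likelihood(state$theta, state$beta,
                                            data$Z, data$obs))), 1e-9)
  }
})

test_that("run_chain is reproducible and both engines agree", {
  data <- make_bvs_instance(n = 30, P = 8, seed = 51)
  hyper <- bvs_hyperparameters(n_iter = 250, burn_in = 50)
  c1 <- run_chain(data, NULL, NULL, hyper, seed = 5, trace = TRUE)
  c2 <- run_chain(data, NULL, NULL, hyper, seed = 5, trace = TRUE)
  expect_identical(c1, c2)
  cr <- run_chain(data, NULL, NULL, hyper, seed = 5, trace = TRUE,
                  engine = "r")
  expect_identical(c1$inclusion_counts, cr$inclusion_counts)
  expect_equal(c1$trace$loglik, cr$trace$loglik, tolerance = 1e-12)
  expect_identical(c1$trace$omega, cr$trace$omega)
})

test_that("perfect-test analysis demands NTFP-truncated panels", {
  expect_error(sr_panels(c("a", "a", "b"), c(2, 4), c(0, 1)),
               "equal length")
  # a negative after a positive is impossible under a perfect test
  one <- sr_panels(rep("a", 2), c(2, 4), c(1, 0))
  expect_error(bvs_data(one, matrix(rnorm(2), 1, 2), test_accuracy(1, 1)),
               "NTFP")
  # row-count mismatch between covariates and panels
  ok <- sr_panels(rep("a", 2), c(2, 4), c(0, 1))
  expect_error(bvs_data(ok, matrix(rnorm(4), 2, 2), test_accuracy(1, 1)),
               "2 rows")
})

test_that("inclusion probabilities rank with stable index tie-breaks", {
  fake <- structure(list(inclusion_counts = setNames(c(60000, 0, 60000, 100),
                                                     paste0("z", 1:4)),
                         kept_iterations = 80000L, P = 4L),
                    class = "chain_summary")
  ip <- inclusion_probabilities(fake)
  expect_equal(ip$probability[ip$index == 1], 0.75)
  expect_equal(ip$index, c(1, 3, 4, 2))   # tie 1 vs 3 broken by index
  expect_true(all(ip$probability >= 0 & ip$probability <= 1))

  zero <- fake
  zero$inclusion_counts[] <- 0L
  expect_equal(inclusion_probabilities(zero)$index, 1:4)

  none <- fake
  none$kept_iterations <- 0L
  expect_error(inclusion_probabilities(none), "kept")
})

test_that("flat likelihood leaves gamma in prior equilibrium", {
  # all-zero covariates make the likelihood independent of gamma, so the
  # chain must sample gamma from its Beta-Bernoulli prior: mean inclusion
  # = w1/(w1+w2)
  panels <- perfect_panels(rep(1:5, times = c(4, 6, 3, 2, 5)))
  Z <- matrix(0, 20, 10)
  data <- bvs_data(panels, Z, test_accuracy(1, 1))
  hyper <- bvs_hyperparameters(n_iter = 4000, burn_in = 500)
  means <- vapply(1:3, function(s) {
    ch <- run_chain(data, NULL, NULL, hyper, seed = 100 + s)
    mean(inclusion_probabilities(ch)$probability)
  }, numeric(1))
  mu <- 5 / 105
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - mu), 3 * se + 0.005)
})

test_that("pure-noise covariates stay at or below the prior mass", {
  # with real (noise) covariates the joint spike-and-slab equilibrium sits
  # at or below the prior inclusion mass (slab Occam penalty)
  acc <- test_accuracy(1, 1)
  des <- simulation_design(n = 60, P = 30, n_true = 0, cir = 0.3,
                           accuracy = acc)
  ds <- simulate_dataset(des, seed = 7)
  hyper <- bvs_hyperparameters(n_iter = 3000, burn_in = 600)
  ch <- run_chain(apply_ntfp(ds$panels), ds$Z, acc, hyper, seed = 77)
  m <- mean(inclusion_probabilities(ch)$probability)
  expect_lt(m, 5 / 105 + 0.03)
})

test_that("strong signals outrank every null covariate in most replicates", {
  acc <- test_accuracy(1, 1)
  hyper <- bvs_hyperparameters(n_iter = 5000, burn_in = 1000)
  hits <- 0
  n_rep <- 8
  for (r in 1:n_rep) {
    des <- simulation_design(n = 100, P = 50, n_true = 5, beta_true = 1,
                             cir = 0.3, accuracy = acc)
    ds <- simulate_dataset(des, seed = 500 + r)
    ch <- run_chain(apply_ntfp(ds$panels), ds$Z, acc, hyper,
                    seed = 600 + r)
    ip <- inclusion_probabilities(ch)
    ptrue <- ip$probability[match(ds$true_idx, ip$index)]
    pnull <- ip$probability[!(ip$index %in% ds$true_idx)]
    if (min(ptrue) > max(pnull)) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.6 * n_rep))
})
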