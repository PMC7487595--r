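test_that("interval partition pools distinct ordered visit times", {
  p <- sr_panels(rep(c("a", "b"), each = 4), rep(c(2, 4, 6, 8), 2),
                 rep(0, 8))
  pt <- build_partition(p)
  expect_equal(pt$tau, c(2, 4, 6, 8))
  expect_equal(pt$J, 4L)

  p2 <- sr_panels(c("a", "a", "b", "b"), c(1, 3, 2, 3), c(0, 0, 0, 1))
  expect_equal(build_partition(p2)$tau, c(1, 2, 3))

  expect_error(sr_panels("a", 0, 0), "finite and > 0")
  expect_error(build_partition(sr_panels(character(0), numeric(0),
                                         integer(0), subjects = "a")),
               "no visits")
})

test_that("panel validation rejects malformed input", {
  expect_error(sr_panels(c("a", "a"), c(2, 2), c(0, 1)), "duplicate")
  expect_error(sr_panels("a", 2, 2), "binary")
  expect_error(sr_panels("a", Inf, 0), "finite")
  expect_error(test_accuracy(0, 0.9), "in \\(0, 1\\]")
  expect_error(test_accuracy(1.1, 0.9), "in \\(0, 1\\]")
})

test_that("observation matrix matches the product construction", {
  p <- sr_panels(rep("a", 4), c(2, 4, 6, 8), c(0, 0, 1, 1))
  pt <- build_partition(p)

  # perfect test: indicator of the bracketed interval (4, 6]
  obs <- observation_matrix(p, pt, test_accuracy(1, 1))
  expect_equal(as.vector(obs$raw), c(0, 0, 1, 0, 0))

  # error-prone test: every entry against the brute-force product
  phi1 <- 0.61; phi0 <- 0.995
  obs2 <- observation_matrix(p, pt, test_accuracy(phi1, phi0))
  for (j in 1:5) {
    expect_equal(unname(obs2$raw[1, j]),
                 brute_force_D(c(2, 4, 6, 8), c(0, 0, 1, 1), pt$tau, j,
                               phi1, phi0),
                 tolerance = 1e-14)
  }
  expect_equal(unname(obs2$raw[1, 3]), 0.995^2 * 0.61^2)

  # differenced rows telescope to the last raw entry
  expect_equal(rowSums(obs2$differenced), obs2$raw[, 5],
               ignore_attr = TRUE)
})

test_that("observation matrix handles zero-visit subjects and errors", {
  # zero-visit subject: empty products give a row of ones, differenced
  # row (1, 0, ..., 0)
  p <- sr_panels(rep("a", 4), c(2, 4, 6, 8), c(0, 0, 1, 1),
                 subjects = c("a", "b"))
  pt <- build_partition(p)
  obs <- observation_matrix(p, pt, test_accuracy(1, 1))
  expect_equal(as.vector(obs$raw["b", ]), rep(1, 5))
  expect_equal(as.vector(obs$differenced["b", ]), c(1, 0, 0, 0, 0))

  # a visit time off the partition grid is an alignment error
  p2 <- sr_panels("a", 3, 1)
  expect_error(observation_matrix(p2, pt, test_accuracy(1, 1)),
               "not on the partition grid")
})

test_that("log-likelihood reproduces hand-computed values", {
  p <- sr_panels(rep("a", 4), c(2, 4, 6, 8), c(0, 0, 1, 1))
  pt <- build_partition(p)
  obs <- observation_matrix(p, pt, test_accuracy(1, 1))
  theta <- rep(0.2, 5)
  expect_equal(as.numeric(log_likelihood(theta, numeric(0), NULL, obs)),
               log(0.2), tolerance = 1e-12)

  # impossible sequence under a perfect test: positive then negative
  bad <- sr_panels(rep("a", 2), c(2, 4), c(1, 0))
  obs_bad <- observation_matrix(bad, build_partition(bad),
                                test_accuracy(1, 1))
  ll <- log_likelihood(c(0.3, 0.3, 0.4), numeric(0), NULL, obs_bad)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "bad_subjects"), "a")
})

test_that("raw and differenced likelihood dialects agree", {
  for (seed in 1:20) {
    inst <- random_instance(n = 20, P = 3, seed = seed)
    theta <- random_theta(ncol(inst$obs$raw))
    beta <- rnorm(3, sd = 0.7)
    l_raw <- as.numeric(log_likelihood(theta, beta, inst$Z, inst$obs))
    l_diff <- log_likelihood(theta, beta, inst$Z, inst$obs,
                             form = "differenced")
    expect_lt(abs(l_raw - l_diff), 1e-10)
  }
})

test_that("perfect-test likelihood reduces to the grouped-PH form", {
  set.seed(4)
  panels <- apply_ntfp(simulate_self_reports(rexp(10, 0.15), c(2, 4, 6, 8),
                                             test_accuracy(1, 1)))
  pt <- build_partition(panels)
  obs <- observation_matrix(panels, pt, test_accuracy(1, 1))
  Z <- matrix(rnorm(10), 10, 1)
  for (r in 1:5) {
    theta <- random_theta(pt$J + 1)
    beta <- rnorm(1)
    expect_equal(as.numeric(log_likelihood(theta, beta, Z, obs)),
                 reference_ic_loglik(panels, theta, beta, Z, pt$tau),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to permuting subjects", {
  inst <- random_instance(n = 15, P = 2, seed = 9)
  theta <- random_theta(ncol(inst$obs$raw))
  beta <- c(0.5, -0.3)
  l1 <- as.numeric(log_likelihood(theta, beta, inst$Z, inst$obs))
  perm <- sample(15)
  obs_p <- inst$obs
  obs_p$raw <- obs_p$raw[perm, ]
  obs_p$differenced <- obs_p$differenced[perm, ]
  l2 <- as.numeric(log_likelihood(theta, beta, inst$Z[perm, , drop = FALSE],
                                  obs_p))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("marginalizing a visit's outcome conserves total probability", {
  # adding a visit and summing the subject likelihood over both possible
  # results must reproduce the likelihood without that visit
  tau <- c(2, 4, 6, 8)
  acc <- test_accuracy(0.7, 0.9)
  theta <- random_theta(5)
  for (seed in 1:10) {
    set.seed(seed)
    n_vis <- sample(1:3, 1)
    times <- sort(sample(tau, n_vis))
    res <- rbinom(n_vis, 1, 0.5)
    extra <- setdiff(tau, times)[1]
    h <- exp(rnorm(1, sd = 0.5))
    lik_of <- function(tms, rs) {
      ord <- order(tms)
      p <- sr_panels(rep("a", length(tms)), tms[ord], rs[ord])
      pt <- structure(list(tau = tau, J = 4L),
                      class = "interval_partition")
      obs <- observation_matrix(p, pt, acc)
      exp(as.numeric(log_likelihood(theta, log(h), matrix(1, 1, 1), obs)))
    }
    base <- lik_of(times, res)
    marg <- lik_of(c(times, extra), c(res, 0L)) +
      lik_of(c(times, extra), c(res, 1L))
    expect_equal(marg, base, tolerance = 1e-12)
  }
})
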