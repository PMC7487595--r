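test_that("baseline hazard calibrates to the cumulative incidence", {
  expect_equal(baseline_hazard_from_cir(0.1, 8), -log(0.9) / 8,
               tolerance = 1e-12)
  expect_equal(baseline_hazard_from_cir(0.3, 8), -log(0.7) / 8,
               tolerance = 1e-12)
  # round trip
  for (cir in c(0.05, 0.1, 0.3, 0.8)) {
    l0 <- baseline_hazard_from_cir(cir, 8)
    expect_lt(abs(1 - exp(-l0 * 8) - cir), 1e-12)
  }
  expect_error(baseline_hazard_from_cir(0, 8), "in \\(0, 1\\)")
  expect_error(baseline_hazard_from_cir(1, 8), "in \\(0, 1\\)")
})

test_that("SNP generator follows Hardy-Weinberg proportions", {
  set.seed(30)
  # q = 0.5: genotype frequencies (0.25, 0.5, 0.25); chi-square GOF should
  # rarely reject at the 0.01 level
  rejections <- 0
  for (k in 1:50) {
    g <- generate_snp_matrix(2000, 1, maf = 0.5, standardize = FALSE)
    obs <- tabulate(as.vector(g) + 1L, 3)
    pval <- suppressWarnings(
      chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value)
    if (pval < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 4)  # 50 trials at the 1% level

  # standardization contract
  Z <- generate_snp_matrix(500, 20)
  expect_true(all(abs(colMeans(Z)) < 1e-8))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-8))
  expect_error(generate_snp_matrix(100, 2, maf = 0.6), "in \\(0, 0.5\\]")

  # default MAF mixture: 26% of columns in the common bin
  set.seed(31)
  q <- attr(generate_snp_matrix(10, 200), "maf")
  expect_equal(sum(q >= 0.35), 52)
  expect_true(all(q >= 0.05 & q <= 0.5))
})

test_that("continuous generator honors exchangeable correlation", {
  set.seed(33)
  Z0 <- generate_continuous_matrix(4000, 6, rho = 0)
  cors <- cor(Z0)[upper.tri(diag(6))]
  expect_true(all(abs(cors) < 4 / sqrt(4000)))

  Z5 <- generate_continuous_matrix(10000, 6, rho = 0.5)
  expect_lt(abs(mean(cor(Z5)[upper.tri(diag(6))]) - 0.5), 0.02)
  expect_true(all(abs(colMeans(Z5)) < 1e-8))
  expect_error(generate_continuous_matrix(10, 2, rho = 1), "\\[0, 1\\)")
})

test_that("event times follow the calibrated PH-exponential model", {
  set.seed(35)
  lam <- baseline_hazard_from_cir(0.3, 8)
  n <- 100000
  X <- simulate_event_times(matrix(0, n, 1), integer(0), 1, lam)
  p <- mean(X <= 8)
  expect_lt(abs(p - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # exponential median = log(2) / rate
  expect_lt(abs(median(X) - log(2) / lam) / (log(2) / lam), 0.02)

  # hazard ratio e^beta ~ 2.718 for a unit shift of the linear predictor
  Z1 <- matrix(1, n, 1)
  X1 <- simulate_event_times(Z1, 1L, 1, lam)
  # exponential: mean = 1/rate, so mean(X)/mean(X1) estimates e^beta
  expect_lt(abs(mean(X) / mean(X1) - exp(1)) / exp(1), 0.03)
})

test_that("self-reports follow the sensitivity/specificity mechanism", {
  set.seed(37)
  # never-event subjects: false positives at rate 1 - phi0
  pan <- simulate_self_reports(rep(Inf, 25000), c(2, 4, 6, 8),
                               test_accuracy(1, 0.9))
  n_pos <- sum(pan$result)
  expect_lt(abs(n_pos / 25000 - 0.4), 3 * sqrt(4 * 0.1 * 0.9 / 25000))

  # post-event visits: positives at rate phi1 = 0.61
  pan2 <- simulate_self_reports(rep(1, 25000), c(2, 4, 6, 8),
                                test_accuracy(0.61, 0.995))
  frac <- mean(pan2$result)
  expect_lt(abs(frac - 0.61), 3 * sqrt(0.61 * 0.39 / nrow(pan2)))

  # perfect test: deterministic reports, first positive at first visit >= X
  pan3 <- simulate_self_reports(c(3, 9, 0.5), c(2, 4, 6, 8),
                                test_accuracy(1, 1))
  per <- split(pan3$result, pan3$subject_id)
  expect_equal(per$s1, c(0, 1, 1, 1))
  expect_equal(per$s2, c(0, 0, 0, 0))
  expect_equal(per$s3, c(1, 1, 1, 1))

  # boundary: a visit exactly at the event time is post-event
  pan4 <- simulate_self_reports(4, c(2, 4, 6, 8), test_accuracy(1, 1))
  expect_equal(pan4$result, c(0, 1, 1, 1))
})

test_that("NTFP truncation discards reports after the first positive", {
  mk <- function(res) sr_panels(rep("a", length(res)),
                                seq_along(res) * 2, res)
  expect_equal(apply_ntfp(mk(c(0, 1, 0, 1)))$result, c(0, 1))
  expect_equal(apply_ntfp(mk(c(0, 0, 0, 0)))$result, c(0, 0, 0, 0))
  expect_equal(apply_ntfp(mk(c(1, 1, 1, 1)))$result, 1)

  # property: at most one positive, and it terminates the panel
  set.seed(39)
  pan <- simulate_self_reports(rexp(200, 0.1), c(2, 4, 6, 8),
                               test_accuracy(0.75, 0.9))
  tr <- apply_ntfp(pan)
  for (v in srbvs:::panel_split(tr)) {
    expect_lte(sum(v$result), 1)
    if (any(v$result == 1)) expect_equal(which(v$result == 1), nrow(v))
  }
})

test_that("dataset generation is deterministic and design-consistent", {
  des <- simulation_design(n = 40, P = 12, n_true = 3, cir = 0.3,
                           accuracy = test_accuracy(0.75, 0.9),
                           design = "ntfp")
  d1 <- simulate_dataset(des, seed = 5)
  d2 <- simulate_dataset(des, seed = 5)
  expect_identical(d1$Z, d2$Z)
  expect_identical(d1$event_times, d2$event_times)
  expect_identical(as.data.frame(d1$panels), as.data.frame(d2$panels))
  expect_length(d1$true_idx, 3)
  # ntfp flag produces truncated panels
  for (v in srbvs:::panel_split(d1$panels)) expect_lte(sum(v$result), 1)

  expect_error(simulation_design(schedule = c(4, 2)), "increasing")
  expect_error(simulation_design(n_true = 200), "exceed")
})
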