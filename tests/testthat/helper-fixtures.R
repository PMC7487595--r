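# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; no data files.

# panels for subjects whose (last-negative, first-positive) bracket is known:
# intervals is a vector of interval indices (1..J+1) on the grid 2,4,6,8;
# reports are the deterministic perfect-test reports, NTFP-truncated.
perfect_panels <- function(intervals, schedule = c(2, 4, 6, 8)) {
  J <- length(schedule)
  ids <- sprintf("s%02d", seq_along(intervals))
  sid <- character(0); tm <- numeric(0); rs <- integer(0)
  for (i in seq_along(intervals)) {
    j <- intervals[i]
    n_vis <- if (j > J) J else j  # visits up to and incl. first positive
    res <- if (j > J) rep(0L, J) else c(rep(0L, j - 1L), 1L)
    sid <- c(sid, rep(ids[i], n_vis))
    tm <- c(tm, schedule[seq_len(n_vis)])
    rs <- c(rs, res)
  }
  sr_panels(sid, tm, rs, subjects = ids)
}

# a random error-prone instance: panels + obs + Z for property tests
random_instance <- function(n = 20, P = 3, seed = 1,
                            accuracy = test_accuracy(0.61, 0.995),
                            schedule = c(2, 4, 6, 8)) {
  set.seed(seed)
  X <- rexp(n, rate = 0.1)
  panels <- simulate_self_reports(X, schedule, accuracy)
  Z <- matrix(rnorm(n * P), n, P)
  partition <- build_partition(panels)
  obs <- observation_matrix(panels, partition, accuracy)
  list(panels = panels, partition = partition, obs = obs, Z = Z,
       accuracy = accuracy)
}

random_theta <- function(Jp1) {
  x <- rexp(Jp1) + 0.05
  x / sum(x)
}

# brute-force observation-matrix entry: direct product over visit
# classifications for hypothesis "event in interval j"
brute_force_D <- function(times, results, tau, j, phi1, phi0) {
  prod(vapply(seq_along(times), function(k) {
    m <- match(times[k], tau)
    if (m <= j - 1) {            # visit strictly before interval j
      if (results[k] == 1) 1 - phi0 else phi0
    } else {                     # visit at or after the event interval
      if (results[k] == 1) phi1 else 1 - phi1
    }
  }, numeric(1)))
}

# textbook grouped-PH interval-censored log-likelihood for perfect tests:
# subject contributes S0(tau_L)^h - S0(tau_R)^h where (tau_L, tau_R] is the
# bracket of last-negative / first-positive visit (tau_R = Inf if none)
reference_ic_loglik <- function(panels, theta, beta, Z, tau) {
  S0 <- c(1, 1 - cumsum(theta))      # S0[j+1] = Pr(X > tau_j)
  per <- split(as.data.frame(panels)[, c("time", "result")],
               factor(panels$subject_id, levels = attr(panels, "subjects")))
  h <- if (is.null(Z)) rep(1, length(per)) else exp(as.vector(Z %*% beta))
  ll <- 0
  for (i in seq_along(per)) {
    v <- per[[i]]
    negs <- v$time[v$result == 0]
    poss <- v$time[v$result == 1]
    L_idx <- if (length(negs)) match(max(negs), tau) else 0
    R_idx <- if (length(poss)) match(min(poss), tau) else length(tau) + 1
    SL <- S0[L_idx + 1]
    SR <- if (R_idx > length(tau)) 0 else S0[R_idx + 1]
    ll <- ll + log(SL^h[i] - SR^h[i])
  }
  ll
}

# random multiplicative perturbation of a theta vector, kept inside the
# optimizer's domain: components >= 1e-10 and exact unit sum (floored
# entries are pinned and only the rest renormalized)
perturb_theta <- function(theta, sd = 0.05, floor = 1e-10) {
  th <- theta * exp(rnorm(length(theta), sd = sd))
  th <- th / sum(th)
  low <- th < floor
  if (any(low)) {
    th[low] <- floor
    th[!low] <- th[!low] * (1 - sum(th[low])) / sum(th[!low])
  }
  th
}
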