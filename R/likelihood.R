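#' Observation matrix for the misclassification-aware likelihood
#'
#' For each subject, column j of the raw matrix is the probability of the
#' observed self-report sequence under the hypothesis that the true event
#' time falls in interval I_j.  A visit at tau_m with m <= j - 1 lies
#' strictly before I_j, so its report is governed by specificity (negative
#' with probability phi0); a visit with m >= j lies at or after the event,
#' so its report is governed by sensitivity (positive with probability
#' phi1).  The differenced matrix C_ij = raw_ij - raw_{i,j-1} (with
#' raw_{i,0} := 0) is carried alongside; both dialects evaluate the same
#' likelihood.
#'
#' @param panels an [sr_panels] object.
#' @param partition an [interval_partition]; every visit time must be on its
#'   grid.
#' @param accuracy a [test_accuracy].
#' @return An object of class `observation_matrix`: list with `raw` and
#'   `differenced` (N x (J+1) matrices, rows named by subject), `subjects`,
#'   `partition` and `accuracy`.
#' @export
observation_matrix <- function(panels, partition, accuracy) {
  stopifnot(inherits(panels, "sr_panels"),
            inherits(partition, "interval_partition"),
            inherits(accuracy, "test_accuracy"))
  tau <- partition$tau
  Jp1 <- partition$J + 1L
  phi1 <- accuracy$sensitivity
  phi0 <- accuracy$specificity
  per <- panel_split(panels)
  N <- length(per)
  raw <- matrix(1, N, Jp1, dimnames = list(names(per), NULL))
  for (i in seq_len(N)) {
    v <- per[[i]]
    if (nrow(v) == 0) next  # empty product: row of ones
    m <- match(v$time, tau)
    if (anyNA(m))
      stop("visit time not on the partition grid for subject ",
           names(per)[i], ": ", v$time[which(is.na(m))[1]])
    pos <- v$result == 1
    # pre-event factor (specificity branch) and post-event factor
    # (sensitivity branch) for each visit
    a0 <- ifelse(pos, 1 - phi0, phi0)
    a1 <- ifelse(pos, phi1, 1 - phi1)
    pre <- cumprod(a0)                 # product over the first k visits
    post <- rev(cumprod(rev(a1)))      # product over visits k..n_i
    for (j in seq_len(Jp1)) {
      npre <- sum(m <= j - 1L)         # visits strictly before I_j
      p1 <- if (npre > 0) pre[npre] else 1
      p2 <- if (npre < length(m)) post[npre + 1L] else 1
      raw[i, j] <- p1 * p2
    }
  }
  differenced <- raw - cbind(0, raw[, -Jp1, drop = FALSE])
  structure(list(raw = raw, differenced = differenced,
                 subjects = names(per), partition = partition,
                 accuracy = accuracy),
            class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat("Observation matrix:", nrow(x$raw), "subjects x", ncol(x$raw),
      "intervals\n")
  invisible(x)
}

# hazard multipliers h_i = exp(z_i' beta); covariate-free model when Z is
# NULL or beta is empty
hazard_mult <- function(Z, beta, n) {
  if (is.null(Z) || length(beta) == 0) return(rep(1, n))
  as.vector(exp(Z %*% beta))
}

#' Misclassification-aware log-likelihood
#'
#' Evaluates the grouped proportional-hazards log-likelihood
#' \deqn{l = \sum_i \log \sum_{j=1}^{J+1} D_{ij} (S_{j-1}^{h_i} - S_j^{h_i}),}
#' where \eqn{h_i = \exp(z_i'\beta)}, \eqn{S_j = \sum_{k>j} \theta_k}
#' (so \eqn{S_0 = 1}, \eqn{S_{J+1} = 0}) and D is the raw observation
#' matrix.  The algebraically identical differenced form
#' \eqn{\sum_j C_{ij} (\sum_{k \ge j} \theta_k)^{h_i}} is available via
#' `form = "differenced"` as an independent computational route.
#'
#' If some subject's likelihood contribution is not positive (an observation
#' impossible under the model, e.g. a negative after a positive with a
#' perfect test), the function returns `-Inf` with the offending subjects
#' flagged in `attr(, "bad_subjects")`.
#'
#' @param theta baseline interval probabilities (length J + 1, positive,
#'   summing to one).
#' @param beta coefficient vector (length P; use `numeric(0)` with
#'   `Z = NULL` for the covariate-free model).
#' @param Z standardized covariate matrix (N x P) or `NULL`.
#' @param obs an [observation_matrix].
#' @param form which algebraic dialect to evaluate.
#' @return Scalar log-likelihood (with attribute `bad_subjects` when
#'   degenerate).
#' @export
log_likelihood <- function(theta, beta, Z, obs,
                           form = c("raw", "differenced")) {
  form <- match.arg(form)
  check_theta(theta, ncol(obs$raw))
  if (!is.null(Z) && nrow(as.matrix(Z)) != nrow(obs$raw))
    stop("covariate rows and observation-matrix rows differ")
  h <- hazard_mult(Z, beta, nrow(obs$raw))
  if (form == "raw") {
    res <- cpp_loglik(obs$raw, h, theta, .theta_eps)
    out <- res$loglik
    if (length(res$bad_subjects))
      attr(out, "bad_subjects") <- obs$subjects[res$bad_subjects]
    out
  } else {
    cpp_loglik_differenced(obs$differenced, h, theta, .theta_eps)
  }
}

check_theta <- function(theta, Jp1) {
  if (length(theta) != Jp1)
    stop("theta must have length J + 1 = ", Jp1)
  if (any(theta <= 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must be positive and sum to one")
  invisible(theta)
}

theta_to_eta <- function(theta) {
  theta <- pmax(theta, .theta_eps)
  log(theta[-length(theta)]) - log(theta[length(theta)])
}

# canonical softmax-with-floor map shared with the compiled profiler, so a
# returned theta and its cached log-likelihood are exactly consistent
eta_to_theta <- function(eta) {
  as.vector(cpp_eta_to_theta(eta, .theta_eps))
}

#' Profile out the baseline interval probabilities
#'
#' Maximizes the log-likelihood over theta on the open simplex for a fixed
#' coefficient vector, using a damped Newton method on the multinomial-logit
#' scale (last interval as reference) with analytic gradient and Hessian.
#' Iterations stop when the log-likelihood improvement falls below 1e-8
#' (at most 200 iterations); on failure one restart from the uniform theta
#' is attempted.
#'
#' @param beta,Z,obs as in [log_likelihood()].
#' @param warm_start optional theta to start from (defaults to uniform).
#' @return List with `theta` (floored at 1e-10 and renormalized), `loglik`,
#'   `converged` and `iters`.  `converged = FALSE` is the explicit failure
#'   signal; callers treating theta as a proposal should reject it.
#' @export
profile_theta <- function(beta, Z, obs, warm_start = NULL) {
  h <- hazard_mult(Z, beta, nrow(obs$raw))
  profile_theta_h(h, obs, warm_start)
}

# internal: profile given precomputed hazard multipliers h = exp(z'beta);
# warm_eta, when given, takes precedence over warm_start (a theta vector)
profile_theta_h <- function(h, obs, warm_start = NULL, warm_eta = NULL) {
  Jp1 <- ncol(obs$raw)
  eta0 <- if (!is.null(warm_eta)) warm_eta
          else if (is.null(warm_start)) rep(0, Jp1 - 1L)
          else theta_to_eta(warm_start)
  res <- cpp_profile_core(obs$raw, obs$differenced, h, eta0, .theta_eps,
                          1e-8, 200L)
  if (!res$converged && !all(eta0 == 0)) {  # one restart from uniform
    res <- cpp_profile_core(obs$raw, obs$differenced, h,
                            rep(0, Jp1 - 1L), .theta_eps, 1e-8, 200L)
  }
  theta <- eta_to_theta(as.vector(res$eta))
  list(theta = theta, eta = as.vector(res$eta), loglik = res$loglik,
       converged = res$converged, iters = res$iters)
}

#' Low-dimensional maximum-likelihood fit
#'
#' Jointly maximizes the misclassification-aware log-likelihood over the
#' regression coefficients and the baseline interval probabilities
#' (numerically, with theta on the multinomial-logit scale), for settings
#' with few covariates (P <= 20 enforced).  Standard errors come from the
#' inverse of a numerically differentiated Hessian at the maximum; Wald
#' statistics and two-sided p-values are reported per coefficient.
#'
#' @param panels an [sr_panels] object.
#' @param Z covariate matrix with few columns (already standardized or on
#'   any fixed scale; no standardization is applied here).
#' @param accuracy a [test_accuracy].
#' @param max_iter maximum BFGS iterations.
#' @return An object of class `srbvs_ml`: list with `beta`, `theta`,
#'   `loglik`, `se`, `z`, `p_value`, `converged`, and the partition.
#' @export
fit_ml <- function(panels, Z, accuracy, max_iter = 500) {
  Z <- as.matrix(Z)
  P <- ncol(Z)
  if (P > 20) stop("fit_ml is for low-dimensional models (P <= 20)")
  partition <- build_partition(panels)
  obs <- observation_matrix(panels, partition, accuracy)
  if (nrow(Z) != nrow(obs$raw))
    stop("covariate rows and panel subjects differ")
  J <- partition$J
  # start from beta = 0 and its profiled theta
  pr0 <- profile_theta(rep(0, P), Z, obs)
  par0 <- c(rep(0, P), theta_to_eta(pr0$theta))
  negll <- function(par) {
    r <- cpp_ml_loglik_grad(obs$raw, obs$differenced, Z, par[seq_len(P)],
                            par[P + seq_len(J)], .theta_eps)
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  grad <- function(par) {
    r <- cpp_ml_loglik_grad(obs$raw, obs$differenced, Z, par[seq_len(P)],
                            par[P + seq_len(J)], .theta_eps)
    if (!is.finite(r$loglik)) return(rep(0, P + J))
    -c(as.vector(r$grad_beta), as.vector(r$grad_eta))
  }
  opt <- optim(par0, negll, grad, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0 && opt$convergence != 1)
    stop("ML optimization failed to converge (code ", opt$convergence, ")")
  beta_hat <- opt$par[seq_len(P)]
  theta_hat <- eta_to_theta(opt$par[P + seq_len(J)])
  H <- fd_hessian(grad, opt$par)
  se <- z <- pv <- rep(NA_real_, P)
  cov_ok <- TRUE
  covb <- tryCatch(solve(H)[seq_len(P), seq_len(P), drop = FALSE],
                   error = function(e) NULL)
  if (is.null(covb) || any(diag(covb) <= 0)) {
    warning("singular or indefinite Hessian: standard errors unavailable")
    cov_ok <- FALSE
  } else {
    se <- sqrt(diag(covb))
    z <- beta_hat / se
    pv <- 2 * pnorm(-abs(z))
  }
  structure(list(beta = setNames(beta_hat, colnames(Z)), theta = theta_hat,
                 loglik = -opt$value, se = se, z = z, p_value = pv,
                 converged = opt$convergence == 0, se_available = cov_ok,
                 partition = partition),
            class = "srbvs_ml")
}

#' @export
print.srbvs_ml <- function(x, ...) {
  cat("Misclassification-aware interval-censored PH fit\n")
  cat("log-likelihood:", format(x$loglik, digits = 8), "\n")
  tab <- data.frame(estimate = x$beta, se = x$se, z = x$z,
                    p_value = x$p_value)
  print(tab, digits = 4)
  invisible(x)
}

# central-difference Jacobian of a gradient function -> Hessian (symmetrized)
fd_hessian <- function(grad_fn, par, h = 1e-5) {
  k <- length(par)
  H <- matrix(0, k, k)
  for (a in seq_len(k)) {
    ea <- rep(0, k); ea[a] <- h
    H[, a] <- (grad_fn(par + ea) - grad_fn(par - ea)) / (2 * h)
  }
  (H + t(H)) / 2
}
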