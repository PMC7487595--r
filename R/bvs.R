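#' Sampler hyperparameters
#'
#' Defaults follow the settings used throughout the package's simulation
#' studies: slab standard deviation b = 1, Beta(5, 100) prior on the
#' inclusion probability omega (prior mean inclusion ~ 4.8%), refine
#' probability p_main = 0.30 per included covariate, 100,000 iterations with
#' the first 20,000 discarded as burn-in.
#'
#' @param b slab standard deviation (> 0).
#' @param w1,w2 Beta prior shapes for omega (> 0).
#' @param p_main probability, per included covariate and iteration, of a
#'   random-walk refinement of its coefficient; in (0, 1).
#' @param n_iter total MCMC iterations.
#' @param burn_in iterations discarded before recording (must be < n_iter).
#' @return An object of class `bvs_hyper`.
#' @export
bvs_hyperparameters <- function(b = 1.0, w1 = 5, w2 = 100, p_main = 0.30,
                                n_iter = 100000L, burn_in = 20000L) {
  stopifnot(b > 0, w1 > 0, w2 > 0, p_main > 0, p_main < 1,
            n_iter >= 1, burn_in >= 0, burn_in < n_iter)
  structure(list(b = b, w1 = w1, w2 = w2, p_main = p_main,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in)),
            class = "bvs_hyper")
}

#' Assemble validated sampler inputs
#'
#' Builds the interval partition and observation matrix and checks the
#' compatibility conditions the sampler relies on.  With a perfect test
#' (sensitivity = specificity = 1) a negative report after a positive one
#' has probability zero, so panels must have been truncated at the first
#' positive (see [apply_ntfp()]); violations are reported with the subject
#' id.
#'
#' @param panels an [sr_panels] object.
#' @param Z standardized covariate matrix with rownames (or row order)
#'   matching the panel roster.
#' @param accuracy a [test_accuracy].
#' @return An object of class `bvs_data` bundling `Z`, `obs`, `partition`
#'   and `accuracy`.
#' @export
bvs_data <- function(panels, Z, accuracy) {
  Z <- as.matrix(Z)
  partition <- build_partition(panels)
  obs <- observation_matrix(panels, partition, accuracy)
  if (nrow(Z) != nrow(obs$raw))
    stop("covariate matrix has ", nrow(Z), " rows but panels have ",
         nrow(obs$raw), " subjects")
  if (is_perfect(accuracy)) {
    bad <- which(apply(obs$raw, 1, max) <= 0)
    if (length(bad))
      stop("perfect-test analysis requires NTFP-truncated panels; ",
           "impossible report sequence for subject ", obs$subjects[bad[1]],
           " (negative after positive)")
  }
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  structure(list(Z = Z, obs = obs, partition = partition,
                 accuracy = accuracy), class = "bvs_data")
}

#' Initialize the sampler state
#'
#' gamma and beta start at zero, omega is drawn from its Beta(w1, w2) prior,
#' and theta is set to the profile maximizer of the log-likelihood at
#' beta = 0.
#'
#' @param data a [bvs_data] object.
#' @param hyper a [bvs_hyperparameters] object.
#' @return A `bvs_state`: list with `gamma`, `beta`, `omega`, `theta`,
#'   `loglik`, `lp` (cached linear predictor) and `K` (number included).
#' @export
initialize_state <- function(data, hyper) {
  P <- ncol(data$Z)
  N <- nrow(data$Z)
  omega <- rbeta(1, hyper$w1, hyper$w2)
  pr <- profile_theta_h(rep(1, N), data$obs)
  if (!pr$converged)
    stop("profile optimization failed at initialization; ",
         "check panels and accuracy values")
  structure(list(gamma = integer(P), beta = numeric(P), omega = omega,
                 theta = pr$theta, eta = pr$eta, loglik = pr$loglik,
                 lp = numeric(N), K = 0L),
            class = "bvs_state")
}

#' Add/remove (flip) move
#'
#' Picks one covariate uniformly at random and proposes flipping its
#' inclusion indicator.  A covariate being switched on receives a
#' coefficient drawn from the slab N(0, b^2); one being switched off has its
#' coefficient set exactly to zero.  theta is re-profiled at the proposed
#' beta, and the proposal is accepted with probability min(exp(Delta), 1)
#' where
#' \deqn{\Delta = l(\theta^*, \beta^*) - l(\theta, \beta)
#'   + (2\gamma_p^* - 1) \log(\omega / (1 - \omega)).}
#' The slab prior and proposal densities for the entering (or leaving)
#' coefficient cancel, leaving exactly this expression.
#'
#' @param state a `bvs_state`.
#' @param data a [bvs_data].
#' @param hyper a [bvs_hyperparameters].
#' @return List with `state` (updated or unchanged), `accepted`, the
#'   proposed covariate `p`, and `delta`.
#' @export
flip_move <- function(state, data, hyper) {
  P <- ncol(data$Z)
  p <- min(floor(runif(1) * P) + 1L, P)
  gamma_new <- 1L - state$gamma[p]
  beta_p <- if (gamma_new == 1L) rnorm(1, 0, hyper$b) else 0
  lp_new <- state$lp + data$Z[, p] * (beta_p - state$beta[p])
  pr <- profile_theta_h(exp(lp_new), data$obs, warm_eta = state$eta)
  if (!pr$converged || !is.finite(pr$loglik)) {
    runif(1)  # keep the RNG stream aligned with the accept/reject draw
    return(list(state = state, accepted = FALSE, p = p, delta = -Inf))
  }
  delta <- pr$loglik - state$loglik +
    (2 * gamma_new - 1) * log(state$omega / (1 - state$omega))
  accepted <- log(runif(1)) < delta
  if (accepted) {
    state$gamma[p] <- gamma_new
    state$beta[p] <- beta_p
    state$lp <- lp_new
    state$theta <- pr$theta
    state$eta <- pr$eta
    state$loglik <- pr$loglik
    state$K <- sum(state$gamma)
  }
  list(state = state, accepted = accepted, p = p, delta = delta,
       proposal = list(gamma_p = gamma_new, beta_p = beta_p,
                       theta = pr$theta, loglik = pr$loglik))
}

#' Coefficient refinement move
#'
#' Random-walk update of the coefficient of an included covariate:
#' beta_p* ~ N(beta_p, b^2), theta re-profiled, accepted with probability
#' min(exp(Delta), 1) where
#' \deqn{\Delta = l(\theta^*, \beta^*) - l(\theta, \beta)
#'   + (\beta_p^2 - \beta_p^{*2}) / (2 b^2),}
#' the second term being the slab-prior ratio (the symmetric proposal
#' cancels).
#'
#' @param state a `bvs_state`.
#' @param data a [bvs_data].
#' @param hyper a [bvs_hyperparameters].
#' @param p index of an included covariate (gamma_p = 1).
#' @return List with `state`, `accepted` and `delta`.
#' @export
refine_move <- function(state, data, hyper, p) {
  if (state$gamma[p] != 1L)
    stop("refine_move called on an excluded covariate (gamma = 0)")
  beta_p <- state$beta[p] + hyper$b * rnorm(1)
  lp_new <- state$lp + data$Z[, p] * (beta_p - state$beta[p])
  pr <- profile_theta_h(exp(lp_new), data$obs, warm_eta = state$eta)
  if (!pr$converged || !is.finite(pr$loglik)) {
    runif(1)
    return(list(state = state, accepted = FALSE, delta = -Inf))
  }
  delta <- pr$loglik - state$loglik +
    (state$beta[p]^2 - beta_p^2) / (2 * hyper$b^2)
  accepted <- log(runif(1)) < delta
  if (accepted) {
    state$beta[p] <- beta_p
    state$lp <- lp_new
    state$theta <- pr$theta
    state$eta <- pr$eta
    state$loglik <- pr$loglik
  }
  list(state = state, accepted = accepted, delta = delta,
       proposal = list(beta_p = beta_p, theta = pr$theta,
                       loglik = pr$loglik))
}

#' Conjugate Gibbs update of the inclusion probability
#'
#' Draws omega from its full conditional Beta(w1 + K, w2 + P - K), where K
#' is the current number of included covariates.
#'
#' @param state a `bvs_state`.
#' @param hyper a [bvs_hyperparameters].
#' @param P number of covariates.
#' @return The new omega.
#' @export
gibbs_omega <- function(state, hyper, P) {
  rbeta(1, hyper$w1 + state$K, hyper$w2 + P - state$K)
}

#' Run the spike-and-slab chain
#'
#' Each iteration performs, in order: one [flip_move()]; then, for each
#' currently included covariate independently with probability `p_main`, one
#' [refine_move()] (each with its own theta re-profiling and accept/reject);
#' then one [gibbs_omega()] draw.  Inclusion indicators are recorded after
#' burn-in.  The run is fully reproducible from `seed`.
#'
#' @param panels an [sr_panels] object (NTFP-truncated if `accuracy` is the
#'   perfect test).
#' @param Z standardized covariate matrix.
#' @param accuracy a [test_accuracy] used in the likelihood (not necessarily
#'   the one that generated the data).
#' @param hyper a [bvs_hyperparameters].
#' @param seed integer seed for the chain.
#' @param trace if `TRUE`, keep a per-iteration trace of (K, loglik, omega).
#' @param engine `"cpp"` (default) runs the compiled iteration loop;
#'   `"r"` runs the same loop composed from the exported R-level moves.
#'   Both consume the RNG stream in the same draw order.
#' @return An object of class `chain_summary`: `inclusion_counts` (named per
#'   covariate), `kept_iterations`, `P`, acceptance rates for flip and
#'   refine moves, profile-failure count, `seed`, `hyper`, and optional
#'   `trace` data frame.
#' @export
run_chain <- function(panels, Z, accuracy, hyper = bvs_hyperparameters(),
                      seed = 1L, trace = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  data <- if (inherits(panels, "bvs_data")) panels
          else bvs_data(panels, Z, accuracy)
  P <- ncol(data$Z)
  set.seed(seed)
  state <- initialize_state(data, hyper)
  if (engine == "cpp") {
    res <- cpp_run_chain(data$obs$raw, data$obs$differenced, data$Z,
                         hyper$b, hyper$w1, hyper$w2, hyper$p_main,
                         hyper$n_iter, hyper$burn_in, state$omega,
                         state$eta, state$loglik, .theta_eps, trace)
    tr <- if (trace) {
      data.frame(iter = seq_len(hyper$n_iter), K = as.integer(res$trace_K),
                 loglik = as.numeric(res$trace_loglik),
                 omega = as.numeric(res$trace_omega))
    } else NULL
    return(structure(
      list(inclusion_counts = setNames(as.integer(res$counts),
                                       colnames(data$Z)),
           kept_iterations = res$kept, P = P,
           flip_acceptance = res$flip_acc / hyper$n_iter,
           refine_acceptance = if (res$ref_tot > 0)
             res$ref_acc / res$ref_tot else NA_real_,
           profile_failures = res$fail,
           seed = seed, hyper = hyper, trace = tr),
      class = "chain_summary"))
  }
  counts <- integer(P)
  kept <- 0L
  flip_acc <- ref_acc <- ref_tot <- fail <- 0L
  tr <- if (trace) {
    data.frame(iter = seq_len(hyper$n_iter), K = NA_integer_,
               loglik = NA_real_, omega = NA_real_)
  } else NULL
  for (it in seq_len(hyper$n_iter)) {
    fm <- flip_move(state, data, hyper)
    state <- fm$state
    if (fm$accepted) flip_acc <- flip_acc + 1L
    if (identical(fm$delta, -Inf)) fail <- fail + 1L
    for (p in which(state$gamma == 1L)) {
      if (runif(1) < hyper$p_main) {
        rm_ <- refine_move(state, data, hyper, p)
        state <- rm_$state
        ref_tot <- ref_tot + 1L
        if (rm_$accepted) ref_acc <- ref_acc + 1L
        if (identical(rm_$delta, -Inf)) fail <- fail + 1L
      }
    }
    state$omega <- gibbs_omega(state, hyper, P)
    if (it > hyper$burn_in) {
      counts <- counts + state$gamma
      kept <- kept + 1L
    }
    if (trace) {
      tr$K[it] <- state$K
      tr$loglik[it] <- state$loglik
      tr$omega[it] <- state$omega
    }
  }
  structure(list(inclusion_counts = setNames(counts, colnames(data$Z)),
                 kept_iterations = kept, P = P,
                 flip_acceptance = flip_acc / hyper$n_iter,
                 refine_acceptance = if (ref_tot > 0) ref_acc / ref_tot else NA_real_,
                 profile_failures = fail,
                 seed = seed, hyper = hyper, trace = tr),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat("Spike-and-slab chain:", x$P, "covariates,", x$kept_iterations,
      "kept iterations (seed", paste0(x$seed, ")\n"))
  cat(sprintf("flip acceptance %.3f; refine acceptance %s\n",
              x$flip_acceptance,
              ifelse(is.na(x$refine_acceptance), "-",
                     sprintf("%.3f", x$refine_acceptance))))
  ip <- inclusion_probabilities(x)
  cat("top covariates:\n")
  print(utils::head(ip, 5), row.names = FALSE)
  invisible(x)
}

#' Posterior inclusion probabilities and ranking
#'
#' probability_p = inclusion_counts_p / kept_iterations; covariates are
#' ranked from most to least important by descending probability, ties
#' broken by ascending covariate index (stable).
#'
#' @param summary a `chain_summary`.
#' @return Data frame with columns `covariate`, `index`, `probability`,
#'   `rank`, sorted by rank.
#' @export
inclusion_probabilities <- function(summary) {
  if (summary$kept_iterations <= 0)
    stop("no kept iterations: burn-in consumed the whole chain")
  prob <- as.numeric(summary$inclusion_counts) / summary$kept_iterations
  idx <- seq_along(prob)
  ord <- order(-prob, idx)
  out <- data.frame(covariate = names(summary$inclusion_counts)[ord],
                    index = idx[ord], probability = prob[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
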