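#' Baseline hazard from a reference-group cumulative incidence
#'
#' With exponential event times in the covariate reference group, an
#' end-of-study cumulative incidence CIR over T years implies
#' lambda0 = -log(1 - CIR) / T.
#'
#' @param cir cumulative incidence in (0, 1).
#' @param T study duration in years (> 0).
#' @return The baseline hazard rate lambda0 (events per year).
#' @examples
#' baseline_hazard_from_cir(0.3, 8)
#' @export
baseline_hazard_from_cir <- function(cir, T = 8) {
  if (!is.numeric(cir) || length(cir) != 1 || is.na(cir) ||
      cir <= 0 || cir >= 1)
    stop("cir must be a single number in (0, 1)")
  if (T <= 0) stop("study duration must be positive")
  -log(1 - cir) / T
}

#' Generate a Hardy-Weinberg SNP design matrix
#'
#' Each column is a SNP with minor allele frequency q drawn from the
#' requested specification, genotypes sampled under Hardy-Weinberg
#' proportions ((1-q)^2, 2q(1-q), q^2), additively coded 0/1/2 (copies of
#' the minor allele), then standardized.  The default MAF specification
#' draws 74% of columns from Uniform(0.05, 0.35) and the rest from
#' Uniform(0.35, 0.5), emulating a GWAS-derived design with a realistic MAF
#' spectrum.  A column that comes out monomorphic is resampled (the additive
#' coding of a constant column carries no information and cannot be
#' standardized).
#'
#' @param n subjects (rows).
#' @param P SNPs (columns).
#' @param maf optional vector of per-column MAFs in (0, 0.5]; recycled.
#' @param standardize center/scale columns (default `TRUE`).
#' @return n x P numeric matrix with columns named snp1..snpP and attribute
#'   `maf` recording the frequencies used.
#' @export
generate_snp_matrix <- function(n, P, maf = NULL, standardize = TRUE) {
  if (is.null(maf)) {
    n_common <- round(0.26 * P)
    q <- c(runif(P - n_common, 0.05, 0.35), runif(n_common, 0.35, 0.5))
    q <- q[sample.int(P)]
  } else {
    q <- rep_len(maf, P)
    if (any(q <= 0 | q > 0.5)) stop("minor allele frequencies must be in (0, 0.5]")
  }
  Z <- matrix(0L, n, P)
  for (p in seq_len(P)) {
    probs <- c((1 - q[p])^2, 2 * q[p] * (1 - q[p]), q[p]^2)
    g <- sample(0:2, n, replace = TRUE, prob = probs)
    tries <- 0
    while (length(unique(g)) == 1L && tries < 100) {
      g <- sample(0:2, n, replace = TRUE, prob = probs)
      tries <- tries + 1
    }
    if (length(unique(g)) == 1L)
      stop("monomorphic SNP column after resampling (MAF too extreme for n)")
    Z[, p] <- g
  }
  colnames(Z) <- paste0("snp", seq_len(P))
  out <- if (standardize) standardize_covariates(Z) else Z
  attr(out, "maf") <- q
  out
}

#' Generate a standardized Gaussian design matrix
#'
#' Continuous features with optional exchangeable correlation rho, emulating
#' e.g. metabolomics panels; columns are standardized to mean 0, unit sample
#' SD.
#'
#' @param n subjects.
#' @param P features.
#' @param rho exchangeable pairwise correlation in [0, 1).
#' @return n x P matrix with columns named x1..xP.
#' @export
generate_continuous_matrix <- function(n, P, rho = 0) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must be in [0, 1) for an exchangeable correlation")
  Z <- matrix(rnorm(n * P), n, P)
  if (rho > 0) {
    common <- rnorm(n)
    Z <- sqrt(rho) * common + sqrt(1 - rho) * Z
  }
  colnames(Z) <- paste0("x", seq_len(P))
  standardize_covariates(Z)
}

#' Simulate exponential event times under the proportional-hazards model
#'
#' X_i ~ Exponential(rate lambda0 * exp(sum_{p in true_idx} beta_true *
#' z_ip)).  No administrative truncation is applied; censoring arises later
#' from the visit schedule (a subject whose event falls after the last visit
#' is effectively right-censored).
#'
#' @param Z covariate matrix.
#' @param true_idx column indices carrying true effects.
#' @param beta_true common true coefficient.
#' @param lambda0 baseline hazard (> 0).
#' @return Numeric vector of event times (years).
#' @export
simulate_event_times <- function(Z, true_idx, beta_true, lambda0) {
  if (lambda0 <= 0) stop("lambda0 must be positive")
  lp <- if (length(true_idx))
    as.vector(Z[, true_idx, drop = FALSE] %*% rep(beta_true, length(true_idx)))
  else rep(0, nrow(Z))
  rexp(nrow(Z), rate = 1) / (lambda0 * exp(lp))
}

#' Simulate error-prone self-reports at scheduled visits
#'
#' Independently at each visit, the probability of a positive report is the
#' sensitivity phi1 if the visit time is at or after the true event time
#' (a visit exactly at the event counts as post-event) and 1 - specificity
#' phi0 otherwise.  Use `X = Inf` for subjects who never experience the
#' event.
#'
#' @param event_times per-subject true event times.
#' @param schedule strictly increasing visit times shared by all subjects.
#' @param accuracy a [test_accuracy].
#' @return An [sr_panels] object with subjects `s1..sN`.
#' @export
simulate_self_reports <- function(event_times, schedule, accuracy) {
  if (length(schedule) == 0 || is.unsorted(schedule, strictly = TRUE))
    stop("schedule must be nonempty and strictly increasing")
  n <- length(event_times)
  K <- length(schedule)
  post <- outer(event_times, schedule, function(x, t) t >= x)
  pplus <- ifelse(post, accuracy$sensitivity, 1 - accuracy$specificity)
  res <- matrix(rbinom(n * K, 1, as.vector(pplus)), n, K)
  ids <- paste0("s", seq_len(n))
  sr_panels(rep(ids, each = K), rep(schedule, times = n),
            as.vector(t(res)), subjects = ids)
}

#' Truncate panels at the first positive report (NTFP design)
#'
#' All visits after a subject's first positive self-report are discarded;
#' the first positive itself is retained.  All-negative panels are
#' unchanged.
#'
#' @param panels an [sr_panels] object.
#' @return The truncated [sr_panels].
#' @export
apply_ntfp <- function(panels) {
  keep <- unlist(lapply(panel_split(panels), function(v) {
    if (nrow(v) == 0) return(logical(0))
    fp <- match(1L, v$result)
    if (is.na(fp)) rep(TRUE, nrow(v)) else seq_len(nrow(v)) <= fp
  }), use.names = FALSE)
  sr_panels(panels$subject_id[keep], panels$time[keep], panels$result[keep],
            subjects = panel_subjects(panels))
}

#' Simulation design
#'
#' Bundles the generative parameters of a synthetic study: n subjects,
#' P covariates, `n_true` randomly placed true effects of size `beta_true`,
#' exponential event times calibrated so the reference group reaches
#' cumulative incidence `cir` by year `T`, a shared visit schedule, the
#' self-report accuracy, and the design flag (`"nmiss"` keeps all scheduled
#' visits, `"ntfp"` truncates at the first positive).
#'
#' @param n,P dimensions of the design.
#' @param n_true number of true effects.
#' @param beta_true effect size on the log-hazard scale.
#' @param cir reference-group cumulative incidence over the study.
#' @param T study duration in years.
#' @param schedule visit times (strictly increasing, within (0, T]).
#' @param accuracy a [test_accuracy] generating the reports.
#' @param design `"nmiss"` or `"ntfp"`.
#' @param covariates `"snp"` (Hardy-Weinberg, default) or `"continuous"`.
#' @param rho exchangeable correlation for continuous designs.
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n = 100, P = 100, n_true = 5, beta_true = 1.0,
                              cir = 0.1, T = 8, schedule = c(2, 4, 6, 8),
                              accuracy = test_accuracy(1, 1),
                              design = c("nmiss", "ntfp"),
                              covariates = c("snp", "continuous"), rho = 0) {
  design <- match.arg(design)
  covariates <- match.arg(covariates)
  if (n_true > P) stop("n_true cannot exceed P")
  if (is.unsorted(schedule, strictly = TRUE) || any(schedule <= 0) ||
      any(schedule > T))
    stop("schedule must be strictly increasing within (0, T]")
  structure(list(n = n, P = P, n_true = n_true, beta_true = beta_true,
                 cir = cir, T = T,
                 lambda0 = baseline_hazard_from_cir(cir, T),
                 schedule = schedule, accuracy = accuracy, design = design,
                 covariates = covariates, rho = rho),
            class = "simulation_design")
}

#' Draw one synthetic dataset
#'
#' Generates the covariate matrix, samples `n_true` true-effect columns
#' uniformly without replacement, draws exponential event times under the
#' proportional-hazards model, and simulates Bernoulli self-reports at the
#' scheduled visits (truncated at the first positive when the design flag is
#' `"ntfp"`).
#'
#' @param design a [simulation_design].
#' @param seed integer seed (the draw is fully reproducible from it).
#' @return List with `Z`, `true_idx`, `event_times`, `panels` and the
#'   `design` echo.
#' @export
simulate_dataset <- function(design, seed = 1L) {
  set.seed(seed)
  Z <- if (design$covariates == "snp")
    generate_snp_matrix(design$n, design$P)
  else generate_continuous_matrix(design$n, design$P, design$rho)
  true_idx <- sort(sample.int(design$P, design$n_true))
  X <- simulate_event_times(Z, true_idx, design$beta_true, design$lambda0)
  panels <- simulate_self_reports(X, design$schedule, design$accuracy)
  if (design$design == "ntfp") panels <- apply_ntfp(panels)
  list(Z = Z, true_idx = true_idx, event_times = X, panels = panels,
       design = design, seed = seed)
}
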