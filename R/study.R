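#' Fraction of true effects ranked in the top k
#'
#' @param ranking permutation of covariate indices, most important first
#'   (e.g. `inclusion_probabilities(chain)$index`).
#' @param true_idx indices of the true effects (nonempty).
#' @param k top-k cutoff (<= number of covariates).
#' @return Fraction of `true_idx` whose rank is <= k, in [0, 1].
#' @examples
#' top_k_true_probability(c(3, 1, 4, 2, 5), true_idx = c(1, 3), k = 2)
#' @export
top_k_true_probability <- function(ranking, true_idx, k = 5) {
  if (k > length(ranking)) stop("k exceeds the number of ranked covariates")
  if (length(true_idx) < 1) stop("true_idx must be nonempty")
  mean(true_idx %in% ranking[seq_len(k)])
}

#' Count of null covariates ranked in the top k
#'
#' @inheritParams top_k_true_probability
#' @return Number of non-true covariates among the top k.
#' @export
top_k_false_positives <- function(ranking, true_idx, k = 5) {
  if (k > length(ranking)) stop("k exceeds the number of ranked covariates")
  sum(!(ranking[seq_len(k)] %in% true_idx))
}

#' Average false positives in the top k over replicates
#'
#' @param rankings list of per-replicate rankings.
#' @param true_idx list (per replicate) or single vector of true indices.
#' @param k top-k cutoff.
#' @return List with `mean` and `se` of the per-replicate false-positive
#'   count.
#' @export
false_positive_summary <- function(rankings, true_idx, k = 5) {
  if (!is.list(true_idx)) true_idx <- rep(list(true_idx), length(rankings))
  fp <- mapply(top_k_false_positives, rankings, true_idx,
               MoreArgs = list(k = k))
  list(mean = mean(fp), se = sd(fp) / sqrt(length(fp)), per_replicate = fp)
}

#' Replication-study configuration
#'
#' @param design a [simulation_design] template; its accuracy is the
#'   data-generating accuracy, and its design flag is ignored (data are
#'   generated with all scheduled visits; truncation is strategy-specific).
#' @param replicates number of simulated datasets R.
#' @param strategies subset of `"bvs_e_nmiss"` (full panels, generating
#'   accuracy), `"bvs_e_ntfp"` (panels truncated at the first positive,
#'   generating accuracy) and `"bvs_perfect"` (truncated panels analysed as
#'   if reports were perfect).
#' @param k top-k cutoff for the accuracy metric.
#' @param hyper sampler hyperparameters.
#' @param seed root seed; replicate r uses the derived seed
#'   `derive_seed(seed, r, s)` for stream s, so any replicate is
#'   reproducible in isolation.
#' @param workers parallel workers for replicates (forked via the parallel
#'   package when > 1); results are independent of the worker count.
#' @param checkpoint optional path to an RDS-free plain CSV checkpoint file;
#'   completed replicates found there are reused.
#' @return An object of class `study_config`.
#' @export
study_config <- function(design, replicates = 200,
                         strategies = c("bvs_perfect", "bvs_e_ntfp",
                                        "bvs_e_nmiss"),
                         k = 5, hyper = bvs_hyperparameters(),
                         seed = 1L, workers = 1L, checkpoint = NULL) {
  strategies <- match.arg(strategies,
                          c("bvs_perfect", "bvs_e_ntfp", "bvs_e_nmiss"),
                          several.ok = TRUE)
  stopifnot(replicates >= 1, k <= design$P)
  structure(list(design = design, replicates = as.integer(replicates),
                 strategies = strategies, k = k, hyper = hyper,
                 seed = as.integer(seed), workers = as.integer(workers),
                 checkpoint = checkpoint),
            class = "study_config")
}

#' Deterministic seed-splitting rule
#'
#' Derives the seed of substream `s` of replicate `r` from the root seed:
#' `(root * 100003 + r * 1009 + s) mod (2^31 - 1)`, mapped away from zero.
#' Documented so any replicate can be re-run in isolation.
#'
#' @param root root seed.
#' @param r replicate number (1-based).
#' @param s substream number (0 = data generation, then one per strategy).
#' @return An integer seed.
#' @export
derive_seed <- function(root, r, s = 0L) {
  x <- (as.numeric(root) * 100003 + as.numeric(r) * 1009 + as.numeric(s)) %%
    2147483647
  as.integer(x) + 1L
}

run_study_replicate <- function(r, config) {
  design <- config$design
  ds <- simulate_dataset(design, seed = derive_seed(config$seed, r, 0L))
  panels_ntfp <- NULL
  out <- list(replicate = r, true_idx = ds$true_idx)
  for (s in seq_along(config$strategies)) {
    strat <- config$strategies[s]
    chain_seed <- derive_seed(config$seed, r, s)
    if (strat == "bvs_e_nmiss") {
      panels <- ds$panels
      acc <- design$accuracy
    } else {
      if (is.null(panels_ntfp)) panels_ntfp <- apply_ntfp(ds$panels)
      panels <- panels_ntfp
      acc <- if (strat == "bvs_perfect") test_accuracy(1, 1)
             else design$accuracy
    }
    chain <- run_chain(panels, ds$Z, acc, config$hyper, seed = chain_seed)
    ranking <- inclusion_probabilities(chain)$index
    out[[strat]] <- list(
      ranking = ranking,
      metric = top_k_true_probability(ranking, ds$true_idx, config$k),
      false_positives = top_k_false_positives(ranking, ds$true_idx,
                                              config$k))
  }
  out
}

#' Run the replication study
#'
#' For each replicate: simulate a dataset with all scheduled visits, then
#' run each configured analysis strategy on it (truncating at the first
#' positive where the strategy requires), rank covariates by posterior
#' inclusion probability, and score the fraction of true effects in the top
#' k.  Results aggregate to a mean metric with Monte-Carlo standard error
#' per strategy.  Fully reproducible from the root seed, independent of the
#' worker count.
#'
#' @param config a [study_config].
#' @return An object of class `study_result`: `table` (one row per strategy
#'   with metric, SE, mean false positives, R), `per_replicate` (long data
#'   frame), `rankings` (list by strategy), `config`.
#' @export
run_replication_study <- function(config) {
  runner <- function(r) try(run_study_replicate(r, config), silent = TRUE)
  reps <- seq_len(config$replicates)
  cached <- list()
  if (!is.null(config$checkpoint) && file.exists(config$checkpoint))
    cached <- read_checkpoint(config$checkpoint, config)
  todo <- setdiff(reps, vapply(cached, `[[`, 0L, "replicate"))
  new_res <- if (config$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(todo, runner, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else if (!is.null(config$checkpoint)) {
    lapply(todo, function(r) {
      res <- runner(r)
      if (!inherits(res, "try-error"))
        append_checkpoint(config$checkpoint, res, config)
      res
    })
  } else {
    lapply(todo, runner)
  }
  results <- c(cached, new_res)
  ord <- order(vapply(results, function(x)
    if (inherits(x, "try-error")) NA_integer_ else x$replicate, 0L),
    na.last = TRUE)
  results <- results[ord]
  failed <- vapply(results, function(x) inherits(x, "try-error"), logical(1))
  if (any(failed)) {
    if (mean(failed) > 0.01)
      stop(sum(failed), " replicate(s) failed; aborting study")
    warning(sum(failed), " replicate(s) failed and were excluded")
    results <- results[!failed]
  }
  per <- do.call(rbind, lapply(results, function(x) {
    do.call(rbind, lapply(config$strategies, function(strat) {
      data.frame(replicate = x$replicate, strategy = strat,
                 metric = x[[strat]]$metric,
                 false_positives = x[[strat]]$false_positives,
                 stringsAsFactors = FALSE)
    }))
  }))
  tab <- do.call(rbind, lapply(config$strategies, function(strat) {
    m <- per$metric[per$strategy == strat]
    fp <- per$false_positives[per$strategy == strat]
    data.frame(strategy = strat, metric = mean(m),
               se = sd(m) / sqrt(length(m)), false_positives = mean(fp),
               replicates = length(m), stringsAsFactors = FALSE)
  }))
  rankings <- lapply(setNames(config$strategies, config$strategies),
                     function(strat)
                       lapply(results, function(x) x[[strat]]$ranking))
  structure(list(table = tab, per_replicate = per, rankings = rankings,
                 true_idx = lapply(results, `[[`, "true_idx"),
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  d <- x$config$design
  cat(sprintf(
    "Replication study: n=%d P=%d CIR=%.2f phi1=%.3g phi0=%.3g R=%d\n",
    d$n, d$P, d$cir, d$accuracy$sensitivity, d$accuracy$specificity,
    x$config$replicates))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}

# -- plain-text checkpointing ------------------------------------------------
# One CSV row per (replicate, strategy); rankings and truths are stored as
# pipe-joined index strings so interrupted studies resume without rerunning
# completed replicates (single-worker runs only append incrementally).

append_checkpoint <- function(path, res, config) {
  rows <- do.call(rbind, lapply(config$strategies, function(strat) {
    data.frame(replicate = res$replicate, strategy = strat,
               metric = res[[strat]]$metric,
               false_positives = res[[strat]]$false_positives,
               ranking = paste(res[[strat]]$ranking, collapse = "|"),
               true_idx = paste(res$true_idx, collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = ",", row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path),
              quote = TRUE)
}

read_checkpoint <- function(path, config) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(list())
  out <- list()
  for (r in unique(df$replicate)) {
    sub <- df[df$replicate == r, ]
    if (!all(config$strategies %in% sub$strategy)) next  # incomplete row set
    res <- list(replicate = as.integer(r),
                true_idx = as.integer(strsplit(sub$true_idx[1], "\\|")[[1]]))
    for (strat in config$strategies) {
      row <- sub[sub$strategy == strat, ][1, ]
      res[[strat]] <- list(
        ranking = as.integer(strsplit(row$ranking, "\\|")[[1]]),
        metric = row$metric, false_positives = row$false_positives)
    }
    out[[length(out) + 1L]] <- res
  }
  out
}

#' Score externally produced rankings
#'
#' Ingests per-replicate rankings produced by another tool (for example a
#' random survival forest comparator) and scores them with the same top-k
#' metric, so external strategies can sit beside the sampler's results.
#'
#' @param path CSV with columns `replicate`, `index`, `rank` (one row per
#'   covariate per replicate).
#' @param result a `study_result` whose per-replicate `true_idx` define the
#'   truths (replicate numbers must match).
#' @param k top-k cutoff (defaults to the study's k).
#' @return Data frame with one row: strategy = file name, metric, se,
#'   false positives.
#' @export
score_external_rankings <- function(path, result, k = result$config$k) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("replicate", "index", "rank")
  if (!all(need %in% names(df)))
    stop("external ranking file must have columns replicate, index, rank")
  metrics <- fps <- numeric(0)
  for (i in seq_along(result$true_idx)) {
    sub <- df[df$replicate == i, ]
    if (nrow(sub) == 0) next
    ranking <- sub$index[order(sub$rank)]
    metrics <- c(metrics, top_k_true_probability(ranking,
                                                 result$true_idx[[i]], k))
    fps <- c(fps, top_k_false_positives(ranking, result$true_idx[[i]], k))
  }
  if (length(metrics) == 0) stop("no replicates matched the study")
  data.frame(strategy = basename(path), metric = mean(metrics),
             se = sd(metrics) / sqrt(length(metrics)),
             false_positives = mean(fps), replicates = length(metrics),
             stringsAsFactors = FALSE)
}
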