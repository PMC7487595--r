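#' Read a covariate matrix from CSV
#'
#' Expects a header row of covariate names and a first column of subject
#' ids.  Missing cells (empty or NA) are imputed to 0 before any
#' standardization — for additively coded genotypes this is imputation to
#' the homozygous-major-allele class — and the imputation count is reported
#' via a message.
#'
#' @param path CSV path.  Lines starting with `#` are ignored.
#' @param standardize center/scale columns after imputation.
#' @return Numeric matrix with subject ids as rownames.
#' @export
read_covariates <- function(path, standardize = TRUE) {
  df <- read.csv(path, check.names = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("covariate file needs an id column plus covariates")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate subject id in covariate file: ",
         ids[duplicated(ids)][1])
  M0 <- as.matrix(df[, -1, drop = FALSE])
  # distinguish genuinely missing cells (empty/NA -> imputed) from
  # non-numeric junk (-> error) before any coercion
  missing_mask <- is.na(M0) | trimws(M0) == ""
  M <- suppressWarnings(array(as.numeric(M0), dim = dim(M0),
                              dimnames = dimnames(M0)))
  bad <- which(!missing_mask & (is.na(M) | !is.finite(M)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(M))
    stop("non-numeric covariate cell at data row ", rc[1], ", column ",
         colnames(M)[rc[2]])
  }
  n_na <- sum(missing_mask)
  if (n_na > 0) {
    M[missing_mask] <- 0
    message(n_na, " missing covariate cell(s) imputed to 0 ",
            "(homozygous major allele for genotype data)")
  }
  rownames(M) <- ids
  if (standardize) M <- standardize_covariates(M)
  rownames(M) <- ids
  M
}

#' Read self-report panels from a long CSV
#'
#' Expects columns `subject_id`, `time` (years), `result` (0/1).  Subjects
#' listed in `roster` (for example the covariate file's ids) but absent from
#' the panel file are an error: a subject with no visits must still appear
#' (with an empty `time`/`result`) so absences are explicit.
#'
#' @param path CSV path.  Lines starting with `#` are ignored.
#' @param roster optional character vector of required subject ids, fixing
#'   the row order of downstream matrices.
#' @return An [sr_panels] object.
#' @export
read_panel <- function(path, roster = NULL) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "result")
  if (!all(need %in% names(df)))
    stop("panel file must have columns subject_id, time, result")
  if (!all(df$result %in% c(0, 1)))
    stop("non-binary result at data row ",
         which(!(df$result %in% c(0, 1)))[1])
  if (any(!is.finite(df$time) | df$time <= 0))
    stop("visit time <= 0 or non-numeric at data row ",
         which(!is.finite(df$time) | df$time <= 0)[1])
  if (!is.null(roster)) {
    missing_ids <- setdiff(roster, df$subject_id)
    if (length(missing_ids))
      stop("subject(s) missing from panel file: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    extra <- setdiff(df$subject_id, roster)
    if (length(extra))
      stop("panel file has subject(s) not in the roster: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  sr_panels(df$subject_id, df$time, df$result, subjects = roster)
}

#' Write self-report panels to CSV
#'
#' @param panels an [sr_panels] object.
#' @param path output CSV path.
#' @export
write_panel <- function(panels, path) {
  write.csv(as.data.frame(panels)[, c("subject_id", "time", "result")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a covariate matrix to CSV
#'
#' @param Z numeric matrix with subject ids as rownames (generated when
#'   absent).
#' @param path output CSV path.
#' @export
write_covariates <- function(Z, path) {
  ids <- rownames(Z)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(Z)))
  df <- data.frame(subject_id = ids, as.data.frame(unclass(Z)[, ,
                   drop = FALSE]), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# short stable hash of a configuration object (polynomial rolling hash over
# its deparse; provenance fingerprint, not cryptographic)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

result_header <- function(seed, config) {
  c(sprintf("# srbvs %s", as.character(packageVersion("srbvs"))),
    sprintf("# seed: %s", paste(seed, collapse = ",")),
    sprintf("# config: %s", config_hash(config)))
}

#' Write analysis results to CSV
#'
#' Dispatches on the result class: a `chain_summary` produces an
#' inclusion-probability table (covariate, index, probability, rank), a
#' `study_result` the per-strategy metric table, and a data frame is
#' written as-is.  Every file starts with `#`-prefixed header lines
#' recording the package version, the seed and a hash of the
#' configuration, so the output is reproducible from its own header.
#'
#' @param x result object.
#' @param path output CSV path.
#' @param seed seed(s) to record (defaults to what the object carries).
#' @export
write_results <- function(x, path, seed = NULL) {
  if (inherits(x, "chain_summary")) {
    df <- inclusion_probabilities(x)
    if (is.null(seed)) seed <- x$seed
    cfg <- x$hyper
  } else if (inherits(x, "study_result")) {
    df <- x$table
    if (is.null(seed)) seed <- x$config$seed
    cfg <- x$config[setdiff(names(x$config), "design")]
  } else if (is.data.frame(x)) {
    df <- x
    cfg <- names(x)
  } else stop("unsupported result object of class ", class(x)[1])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed, cfg), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the truth sidecar of a simulated dataset
#'
#' Records the true-effect indices, the per-subject true event times and
#' the design parameters of a [simulate_dataset()] draw, as a commented CSV.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param path output CSV path.
#' @export
write_truth <- function(dataset, path) {
  d <- dataset$design
  hdr <- c(result_header(dataset$seed, d),
           sprintf("# true_idx: %s", paste(dataset$true_idx, collapse = "|")),
           sprintf("# cir: %g; T: %g; lambda0: %g; beta_true: %g", d$cir,
                   d$T, d$lambda0, d$beta_true),
           sprintf("# sensitivity: %g; specificity: %g; design: %s",
                   d$accuracy$sensitivity, d$accuracy$specificity, d$design))
  ids <- rownames(dataset$Z)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dataset$Z)))
  df <- data.frame(subject_id = ids, event_time = dataset$event_times)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [bvs_hyperparameters()],
#' [simulation_design()] and [study_config()]; the CLI merges them with
#' command-line flags (flags win).
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
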