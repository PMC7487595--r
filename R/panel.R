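#' Self-report visit panels
#'
#' A panel set holds, for every subject, the scheduled visit times (in years
#' since enrollment) and the binary self-report recorded at each visit
#' (1 = positive, 0 = negative).  The time origin is enrollment, at which all
#' subjects are event-free, so visit times must be strictly positive; within
#' a subject, visit times must be strictly increasing.  A subject may have
#' zero visits only if it is listed explicitly via `subjects`.
#'
#' @param subject_id vector of subject identifiers (coerced to character).
#' @param time numeric vector of visit times in years, all finite and > 0.
#' @param result binary vector (0/1 or logical) of self-report results.
#' @param subjects optional character vector fixing the full subject roster
#'   (and its order); subjects without visits are retained with empty panels.
#' @return An object of class `sr_panels`: a data frame with columns
#'   `subject_id`, `time`, `result`, sorted by subject then time, with the
#'   roster in `attr(, "subjects")`.
#' @examples
#' p <- sr_panels(rep("s1", 4), c(2, 4, 6, 8), c(0, 0, 1, 1))
#' build_partition(p)
#' @export
sr_panels <- function(subject_id, time, result, subjects = NULL) {
  n <- length(subject_id)
  if (length(time) != n || length(result) != n)
    stop("subject_id, time and result must have equal length")
  subject_id <- as.character(subject_id)
  time <- as.numeric(time)
  result <- as.integer(result)
  if (n > 0) {
    if (any(!is.finite(time)) || any(time <= 0))
      stop("visit times must be finite and > 0 (time origin is enrollment)")
    if (!all(result %in% c(0L, 1L)))
      stop("self-report results must be binary (0/1)")
  }
  if (is.null(subjects)) {
    subjects <- unique(subject_id)
  } else {
    subjects <- as.character(subjects)
    if (anyDuplicated(subjects))
      stop("duplicate ids in subject roster")
    if (!all(subject_id %in% subjects))
      stop("panel rows reference subjects missing from the roster")
  }
  ord <- order(match(subject_id, subjects), time)
  df <- data.frame(subject_id = subject_id[ord], time = time[ord],
                   result = result[ord], stringsAsFactors = FALSE)
  dup <- duplicated(df[, c("subject_id", "time")])
  if (any(dup))
    stop("duplicate (subject, time) visit: subject ",
         df$subject_id[which(dup)[1]], " at time ", df$time[which(dup)[1]])
  structure(df, subjects = subjects, class = c("sr_panels", "data.frame"))
}

#' @export
print.sr_panels <- function(x, ...) {
  cat("Self-report panels:", length(attr(x, "subjects")), "subjects,",
      nrow(x), "visits\n")
  NextMethod()
}

panel_subjects <- function(panels) attr(panels, "subjects")

# split into per-subject data frames, keeping roster order (zero-visit
# subjects give empty frames)
panel_split <- function(panels) {
  f <- factor(panels$subject_id, levels = panel_subjects(panels))
  split(as.data.frame(panels)[, c("time", "result")], f)
}

#' Build the interval partition from pooled visit times
#'
#' The distinct visit times pooled over all subjects, sorted increasingly,
#' define tau_1 < ... < tau_J and hence J + 1 disjoint intervals
#' (tau_{j-1}, tau_j] for j = 1..J (with tau_0 = 0) plus the no-event
#' interval (tau_J, Inf).
#'
#' @param panels an [sr_panels] object with at least one visit.
#' @return An object of class `interval_partition`: list with `tau`
#'   (ordered distinct visit times) and `J` (its length).
#' @export
build_partition <- function(panels) {
  if (!inherits(panels, "sr_panels")) stop("panels must be an sr_panels object")
  if (nrow(panels) == 0) stop("no visits: cannot build an interval partition")
  tau <- sort(unique(panels$time))
  structure(list(tau = tau, J = length(tau)), class = "interval_partition")
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("Interval partition: J =", x$J, "visit times ->", x$J + 1, "intervals\n")
  cat("tau:", paste(signif(x$tau, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Self-report accuracy
#'
#' Sensitivity is the probability of a positive report at a visit on or after
#' the true event time; specificity is the probability of a negative report
#' at a visit strictly before it.  Both are treated as known constants;
#' `test_accuracy(1, 1)` denotes a perfect test.
#'
#' @param sensitivity,specificity probabilities in (0, 1].
#' @return An object of class `test_accuracy`.
#' @export
test_accuracy <- function(sensitivity, specificity) {
  for (v in c(sensitivity, specificity))
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      stop("sensitivity and specificity must be single numbers in (0, 1]")
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "test_accuracy")
}

#' @export
print.test_accuracy <- function(x, ...) {
  cat(sprintf("Self-report accuracy: sensitivity %.4g, specificity %.4g\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

is_perfect <- function(accuracy)
  accuracy$sensitivity == 1 && accuracy$specificity == 1

#' Standardize a covariate matrix
#'
#' Columns are centered and scaled to unit sample standard deviation
#' (denominator N - 1).  Constant columns cannot be standardized and are
#' rejected.
#'
#' @param Z numeric matrix (subjects in rows).
#' @return The standardized matrix, preserving dimnames.
#' @export
standardize_covariates <- function(Z) {
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) stop("covariate matrix must be numeric")
  s <- apply(Z, 2, sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- which(s == 0 | !is.finite(s))[1]
    stop("constant covariate column cannot be standardized: column ", bad)
  }
  scale(Z, center = TRUE, scale = s)[, , drop = FALSE]
}
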