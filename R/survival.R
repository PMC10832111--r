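#' Bulk cohort with overall survival
#'
#' Container for a samples-by-genes expression matrix plus right-censored
#' overall survival. Expression is standardized per gene within the cohort
#' (mean 0, sd 1); constant genes are dropped. Cohorts intended for
#' cross-validation must each be standardized independently, which this
#' constructor guarantees by standardizing at construction.
#'
#' @param expr Samples-by-genes numeric matrix (raw or already standardized
#'   scale; standardized again here unless `standardize = FALSE`).
#' @param os_time Positive overall-survival times (months), one per sample.
#' @param os_event Event indicators, 1 = death observed, 0 = censored.
#' @param standardize Standardize per gene (default `TRUE`).
#' @return A `cohort_table` with elements `expr`, `os_time`, `os_event`.
#' @export
cohort_table <- function(expr, os_time, os_event, standardize = TRUE) {
  stopifnot(is.matrix(expr), nrow(expr) == length(os_time),
            length(os_time) == length(os_event))
  if (any(os_time <= 0)) stop("survival times must be positive", call. = FALSE)
  if (!all(os_event %in% c(0, 1)))
    stop("os_event must be 0/1", call. = FALSE)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("S%04d", seq_len(nrow(expr)))
  if (standardize) {
    sds <- apply(expr, 2L, stats::sd)
    keep <- !is.na(sds) & sds > 0
    expr <- scale(expr[, keep, drop = FALSE])
    attr(expr, "scaled:center") <- attr(expr, "scaled:scale") <- NULL
  }
  structure(list(expr = expr, os_time = as.numeric(os_time),
                 os_event = as.integer(os_event)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples x %d genes, %d events (%.0f%% censored)\n",
              nrow(x$expr), ncol(x$expr), sum(x$os_event),
              100 * mean(x$os_event == 0)))
  invisible(x)
}

#' @export
score_gene_set.cohort_table <- function(x, gene_set) {
  score_gene_set(t(x$expr), gene_set)
}

#' Subcluster score of bulk samples
#'
#' Per-sample mean standardized expression over a refined marker gene set —
#' the bulk surrogate for the abundance/activity of a single-cell
#' subcluster. Delegates to [score_gene_set()].
#'
#' @param cohort A [cohort_table()].
#' @param refined_set Character vector of (refined) marker genes.
#' @return Named numeric vector, one score per sample.
#' @export
subcluster_score <- function(cohort, refined_set) {
  stopifnot(inherits(cohort, "cohort_table"))
  score_gene_set(cohort, refined_set)
}

#' Two-sample log-rank test
#'
#' Standard log-rank comparison of two right-censored groups: over distinct
#' event times, `statistic = (sum(O - E))^2 / sum(V)`, chi-squared with one
#' degree of freedom. Computed via [survival::survdiff()].
#'
#' @param timesA,eventsA Times and 0/1 event indicators of group A.
#' @param timesB,eventsB Same for group B.
#' @return List with `statistic` (>= 0) and `pvalue`. If neither group has
#'   any event the statistic is 0 and p = 1, with a warning.
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  stopifnot(length(timesA) == length(eventsA),
            length(timesB) == length(eventsB),
            length(timesA) > 0, length(timesB) > 0)
  if (any(c(timesA, timesB) <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (sum(eventsA) + sum(eventsB) == 0) {
    warning("no events in either group; log-rank undefined, p = 1", call. = FALSE)
    return(list(statistic = 0, pvalue = 1))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq),
       pvalue = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Minimum-p log-rank cut-off scan
#'
#' Finds the score cut-off that best separates survival, the way optimal
#' cut-points are chosen for bulk signature scores: candidate cut-offs are
#' every value from the first quartile Q1 upward in steps of `step`, never
#' exceeding the third quartile Q3 (linear-interpolation quantiles). At
#' each candidate `c` samples split into score-high (`score > c`, strict)
#' vs score-low (`score <= c`); candidates leaving a group smaller than
#' `min_group` are skipped (recorded). The candidate with the lowest
#' log-rank p is the optimal cut-off; ties go to the candidate nearest the
#' median score.
#'
#' No multiplicity correction is applied across the grid, so the minimum p
#' is optimistic; see the package vignette for the simulation documenting
#' this.
#'
#' @param scores Numeric per-sample scores.
#' @param os_time,os_event Survival times and 0/1 event indicators.
#' @param step Grid step on the score scale. Default 0.04.
#' @param min_group Minimum group size for a candidate to be evaluated.
#' @return A `cutoff_scan`: `q1`, `q3`, `step`, `candidates`, `pvalues`
#'   (NA where skipped), `skipped`, `optimal_cutoff`, `optimal_p`.
#' @examples
#' set.seed(1)
#' s <- rnorm(120); t <- rexp(120, ifelse(s > 0, 3, 1)); e <- rep(1, 120)
#' scan_cutoff(s, t, e)$optimal_cutoff
#' @export
scan_cutoff <- function(scores, os_time, os_event, step = 0.04, min_group = 5L) {
  stopifnot(length(scores) == length(os_time),
            length(os_time) == length(os_event))
  step <- .assert_positive(step, "step")
  min_group <- .assert_count(min_group, "min_group")
  if (length(scores) < 2L * min_group)
    stop("need at least 2 * min_group samples", call. = FALSE)
  qs <- unname(quantile(scores, c(0.25, 0.75), type = 7))
  q1 <- qs[1L]; q3 <- qs[2L]
  n_steps <- floor((q3 - q1) / step + 1e-9)
  candidates <- q1 + step * (0:n_steps)

  pvals <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    hi <- scores > candidates[i]
    if (sum(hi) < min_group || sum(!hi) < min_group) next
    pvals[i] <- logrank_test(os_time[hi], os_event[hi],
                             os_time[!hi], os_event[!hi])$pvalue
  }
  if (all(is.na(pvals)))
    stop("every candidate cut-off left a group below min_group", call. = FALSE)
  best_p <- min(pvals, na.rm = TRUE)
  best <- which(pvals == best_p)
  if (length(best) > 1L) {
    med <- stats::median(scores)
    best <- best[order(abs(candidates[best] - med))]
  }
  structure(list(q1 = q1, q3 = q3, step = step,
                 candidates = candidates, pvalues = pvals,
                 skipped = candidates[is.na(pvals)],
                 optimal_cutoff = candidates[best[1L]],
                 optimal_p = best_p),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "cutoff_scan: %d candidates on [%.3f, %.3f] step %.3g (%d skipped)\n",
    length(x$candidates), x$q1, x$q3, x$step, length(x$skipped)))
  cat(sprintf("  optimal cut-off %.4f, log-rank p %.3g\n",
              x$optimal_cutoff, x$optimal_p))
  invisible(x)
}

#' Cross-cohort validation of an optimal cut-off
#'
#' Trains the minimum-p cut-off on one cohort and applies the *same score
#' value* to an independent cohort (each cohort standardized on its own),
#' reporting the log-rank p in both. A cut-off that only reflects
#' minimum-p optimism will not transfer; a real prognostic split will.
#'
#' @param train,test [cohort_table()]s, standardized independently.
#' @param refined_set Marker gene set used for [subcluster_score()].
#' @param step,min_group Passed to [scan_cutoff()].
#' @return List with `cutoff`, `p_train`, `p_test`, and the underlying
#'   `scan`. `p_test` is `NA` with a warning if the transferred cut-off
#'   leaves an empty group in the test cohort.
#' @export
cross_validate_cutoff <- function(train, test, refined_set,
                                  step = 0.04, min_group = 5L) {
  stopifnot(inherits(train, "cohort_table"), inherits(test, "cohort_table"))
  sc_train <- subcluster_score(train, refined_set)
  sc_test <- subcluster_score(test, refined_set)
  scan <- scan_cutoff(sc_train, train$os_time, train$os_event,
                      step = step, min_group = min_group)
  cut <- scan$optimal_cutoff
  hi <- sc_test > cut
  if (!any(hi) || all(hi)) {
    warning("transferred cut-off leaves an empty group in the test cohort",
            call. = FALSE)
    p_test <- NA_real_
  } else {
    p_test <- logrank_test(test$os_time[hi], test$os_event[hi],
                           test$os_time[!hi], test$os_event[!hi])$pvalue
  }
  list(cutoff = cut, p_train = scan$optimal_p, p_test = p_test, scan = scan)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator for right-censored data, via
#' [survival::survfit()]. The returned step function is monotone
#' non-increasing with S(0) = 1.
#'
#' @param times Positive survival times.
#' @param events 0/1 event indicators.
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`, `surv`,
#'   beginning at the row `time = 0, surv = 1`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}
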