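#' Confusion counts pooled over all readings of a reader study
#'
#' Each reading (one reader's call on one case) is tallied against the EVLW
#' reference status of the case.  Borderline cases must have been excluded
#' beforehand (as [edema_study()] does) or are rejected here.
#'
#' @param calls Readers x cases call matrix (see [as_call_matrix()]).
#' @param reference An [reference_standard()] covering all cases.
#' @return Object of class `confusion_counts`: list with integer `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
pooled_confusion <- function(calls, reference) {
  check_call_matrix(calls)
  status <- ref_status(reference, colnames(calls))
  if (any(status == "borderline"))
    abort_input(sprintf("borderline cases must be excluded first: %s",
      paste(colnames(calls)[status == "borderline"], collapse = ", ")))
  truth <- matrix(status, nrow(calls), ncol(calls), byrow = TRUE)
  confusion_counts(tp = sum(calls == "edema" & truth == "edema"),
                   fp = sum(calls == "edema" & truth == "no_edema"),
                   tn = sum(calls == "no_edema" & truth == "no_edema"),
                   fn = sum(calls == "no_edema" & truth == "edema"))
}

#' @rdname pooled_confusion
#' @param tp,fp,tn,fn Non-negative integer reading counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    abort_input("confusion counts must be non-negative integers")
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Readings: TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Exact or Wilson confidence interval for a binomial proportion
#'
#' Clopper-Pearson ("exact") intervals come from beta-distribution
#' quantiles: `lower = qbeta(a/2, x, n-x+1)`, `upper = qbeta(1-a/2, x+1,
#' n-x)`, with the degenerate ends pinned to 0 and 1.  Wilson intervals use
#' the score-test inversion without continuity correction.
#'
#' @param successes,trials Integer counts, `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @param level Two-sided confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` on the percentage scale.
#' @examples
#' proportion_ci(54, 70)
#' @export
proportion_ci <- function(successes, trials,
                          method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  x <- successes; n <- trials
  if (n <= 0) abort_input("trials must be positive")
  if (x < 0 || x > n) abort_input("successes must lie in [0, trials]")
  if (level <= 0 || level >= 1) abort_input("level must lie in (0, 1)")
  a <- 1 - level
  if (method == "clopper_pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  100 * c(lower = lo, upper = hi)
}

#' Diagnostic accuracy metrics from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value on the
#' percentage scale, each with a two-sided binomial confidence interval.
#' A predictive value whose denominator is zero (no positive or no negative
#' calls) is reported as undefined (`NA` with `defined = FALSE`), never as
#' 0 or 100.
#'
#' @param counts A [confusion_counts()].
#' @param ci_method,level Passed to [proportion_ci()].
#' @return Object of class `diag_metrics`: a data frame with one row per
#'   metric and columns `metric`, `estimate`, `lower`, `upper`,
#'   `successes`, `trials`, `defined`, plus attributes `ci_method` and
#'   `level`.
#' @examples
#' diagnostic_metrics(confusion_counts(tp = 54, fp = 0, tn = 70, fn = 16))
#' @export
diagnostic_metrics <- function(counts, ci_method = c("clopper_pearson", "wilson"),
                               level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (counts$tp + counts$fn == 0)
    abort_input("no edema readings: sensitivity undefined for the whole study")
  if (counts$tn + counts$fp == 0)
    abort_input("no non-edema readings: specificity undefined for the whole study")
  one <- function(metric, x, n) {
    if (n == 0)
      return(data.frame(metric = metric, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, successes = x, trials = n,
                        defined = FALSE, stringsAsFactors = FALSE))
    ci <- proportion_ci(x, n, ci_method, level)
    data.frame(metric = metric, estimate = 100 * x / n,
               lower = ci[["lower"]], upper = ci[["upper"]],
               successes = x, trials = n, defined = TRUE,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("sensitivity", counts$tp, counts$tp + counts$fn),
    one("specificity", counts$tn, counts$tn + counts$fp),
    one("ppv",         counts$tp, counts$tp + counts$fp),
    one("npv",         counts$tn, counts$tn + counts$fn))
  attr(out, "ci_method") <- ci_method
  attr(out, "level") <- level
  class(out) <- c("diag_metrics", "data.frame")
  out
}

#' @export
print.diag_metrics <- function(x, ...) {
  cat(sprintf("Diagnostic metrics (%s CI, level %.2f)\n",
              attr(x, "ci_method"), attr(x, "level")))
  for (i in seq_len(nrow(x))) {
    if (!x$defined[i]) {
      cat(sprintf("  %-12s undefined (0 %s)\n", x$metric[i],
                  if (x$metric[i] == "ppv") "positive calls" else "negative calls"))
    } else {
      cat(sprintf("  %-12s %6.2f%%  (%5.2f - %6.2f)  [%d/%d]\n",
                  x$metric[i], x$estimate[i], x$lower[i], x$upper[i],
                  x$successes[i], x$trials[i]))
    }
  }
  invisible(x)
}
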