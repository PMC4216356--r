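#' Evaluate a paired two-arm reader study against the EVLW reference
#'
#' The central analysis of the package: given the binary calls of the same
#' readers on the same cases under two approaches — typically the
#' standardized score-based reading (`calls_new`) and the conventional
#' unaided reading (`calls_old`) — and a per-case EVLW reference standard,
#' computes for each arm the pooled confusion counts, sensitivity,
#' specificity, PPV and NPV with binomial confidence intervals, the mean
#' pairwise inter-reader agreement and free-marginal multirater kappa, plus
#' per-reader correct-call summaries and the net reclassification index
#' (pooled and per reader).  Borderline cases (EVLW 9-14 mL/kg) are
#' excluded from all accuracy computations and listed in the result.
#'
#' @param calls_new,calls_old Readers x cases call matrices
#'   (see [as_call_matrix()]) on identical readers and cases.
#' @param reference An [reference_standard()] covering every case.
#' @param ci_method,level Confidence-interval method and level, passed to
#'   [diagnostic_metrics()] and [binary_nri()].
#' @param arm_names Length-2 character: display names for the new and old
#'   arm.
#' @return An object of class `edema_study` with components `arms` (per-arm
#'   list: `counts`, `metrics`, `agreement`, `kappa`, `per_reader` correct
#'   counts), `nri` (pooled `nri_result`), `nri_per_reader`,
#'   `excluded_cases`, `readers`, `cases` and `provenance`.  Methods:
#'   [print.edema_study()], [summary.edema_study()], [coef.edema_study()],
#'   [confint.edema_study()], [plot.edema_study()].
#' @examples
#' study <- example_reader_study()
#' fit <- edema_study(study$calls_score, study$calls_standard, study$reference)
#' coef(fit)["sensitivity.score_based"]
#' @export
edema_study <- function(calls_new, calls_old, reference,
                        ci_method = c("clopper_pearson", "wilson"),
                        level = 0.95,
                        arm_names = c("score_based", "standard")) {
  ci_method <- match.arg(ci_method)
  check_call_matrix(calls_new, "calls_new")
  check_call_matrix(calls_old, "calls_old")
  if (!identical(dimnames(calls_new), dimnames(calls_old)))
    abort_pairing("the two arms must share readers and cases (paired design)")
  if (length(arm_names) != 2) abort_input("arm_names must have length 2")

  kept <- exclude_borderline(calls_new, reference)
  status <- kept$status

  arm_eval <- function(calls_full) {
    calls <- exclude_borderline(calls_full, reference)$calls
    counts <- pooled_confusion_kept(calls, status)
    per_reader <- per_reader_correct(calls, status)
    p0 <- pairwise_agreement(calls)
    list(counts = counts,
         metrics = diagnostic_metrics(counts, ci_method, level),
         agreement = p0,
         kappa = free_marginal_kappa(p0, 2L),
         per_reader = per_reader)
  }

  arms <- list(arm_eval(calls_new), arm_eval(calls_old))
  names(arms) <- arm_names

  structure(list(
    arms = arms,
    nri = binary_nri(calls_old, calls_new, reference, "pooled", level),
    nri_per_reader = binary_nri(calls_old, calls_new, reference,
                                "per_reader", level),
    excluded_cases = kept$excluded,
    readers = rownames(calls_new),
    cases = colnames(kept$calls),
    provenance = list(
      tool = "edemascore",
      version = as.character(utils::packageVersion("edemascore")),
      rubric_checksum = rubric_checksum(edema_rubric()),
      ci_method = ci_method,
      level = level
    )
  ), class = "edema_study")
}

# confusion from an already-filtered matrix + aligned status vector
pooled_confusion_kept <- function(calls, status) {
  truth <- matrix(status, nrow(calls), ncol(calls), byrow = TRUE)
  confusion_counts(tp = sum(calls == "edema" & truth == "edema"),
                   fp = sum(calls == "edema" & truth == "no_edema"),
                   tn = sum(calls == "no_edema" & truth == "no_edema"),
                   fn = sum(calls == "no_edema" & truth == "edema"))
}

# per-reader counts of correct calls in each truth group
per_reader_correct <- function(calls, status) {
  ev <- status == "edema"
  data.frame(
    reader_id = rownames(calls),
    correct_edema = apply(calls[, ev, drop = FALSE], 1,
                          function(x) sum(x == "edema")),
    n_edema = sum(ev),
    correct_no_edema = apply(calls[, !ev, drop = FALSE], 1,
                             function(x) sum(x == "no_edema")),
    n_no_edema = sum(!ev),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.edema_study <- function(x, ...) {
  cat(sprintf("Paired reader study: %d readers, %d cases", length(x$readers),
              length(x$cases)))
  if (length(x$excluded_cases))
    cat(sprintf(" (%d borderline cases excluded)", length(x$excluded_cases)))
  cat("\n\n")
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("Arm '%s':\n", arm))
    print(a$counts)
    print(a$metrics)
    cat(sprintf("  agreement P0 %.4f, free-marginal kappa %.2f\n\n",
                a$agreement, a$kappa))
  }
  cat(sprintf("Pooled NRI (%s vs %s):\n", names(x$arms)[1], names(x$arms)[2]))
  print(x$nri)
  invisible(x)
}

#' Per-reader summary of a paired reader study
#'
#' @param object An [edema_study()] fit.
#' @param ... Unused.
#' @return Object of class `summary.edema_study`: the fit plus a
#'   `per_reader` data frame (correct counts per arm and per truth group,
#'   per-reader NRI with CI and p) and a `correct_summary` data frame of
#'   means and standard deviations of the per-reader correct counts.
#' @export
summary.edema_study <- function(object, ...) {
  arms <- names(object$arms)
  pr_new <- object$arms[[1]]$per_reader
  pr_old <- object$arms[[2]]$per_reader
  nri <- object$nri_per_reader
  per_reader <- data.frame(
    reader_id = pr_new$reader_id,
    stringsAsFactors = FALSE)
  per_reader[[paste0("correct_edema_", arms[1])]] <- pr_new$correct_edema
  per_reader[[paste0("correct_no_edema_", arms[1])]] <- pr_new$correct_no_edema
  per_reader[[paste0("correct_edema_", arms[2])]] <- pr_old$correct_edema
  per_reader[[paste0("correct_no_edema_", arms[2])]] <- pr_old$correct_no_edema
  per_reader$nri <- vapply(nri[pr_new$reader_id], `[[`, numeric(1), "nri")
  per_reader$nri_lower <- vapply(nri[pr_new$reader_id],
                                 function(z) z$ci[["lower"]], numeric(1))
  per_reader$nri_upper <- vapply(nri[pr_new$reader_id],
                                 function(z) z$ci[["upper"]], numeric(1))
  per_reader$nri_p <- vapply(nri[pr_new$reader_id], `[[`, numeric(1), "p_value")

  correct_summary <- do.call(rbind, lapply(arms, function(arm) {
    pr <- object$arms[[arm]]$per_reader
    data.frame(arm = arm,
               group = c("edema", "no_edema"),
               mean = c(mean(pr$correct_edema), mean(pr$correct_no_edema)),
               sd = c(stats::sd(pr$correct_edema), stats::sd(pr$correct_no_edema)),
               n_cases = c(pr$n_edema[1], pr$n_no_edema[1]),
               stringsAsFactors = FALSE)
  }))
  rownames(correct_summary) <- NULL

  structure(list(study = object, per_reader = per_reader,
                 correct_summary = correct_summary),
            class = "summary.edema_study")
}

#' @export
print.summary.edema_study <- function(x, ...) {
  print(x$study)
  cat("\nPer-reader correct calls and NRI:\n")
  print(x$per_reader, digits = 3, row.names = FALSE)
  cat("\nCorrect-call summaries (mean +/- sd over readers):\n")
  print(x$correct_summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Point estimates of a reader-study fit
#'
#' @param object An [edema_study()] fit.
#' @param ... Unused.
#' @return Named numeric vector: `sensitivity`, `specificity`, `ppv`,
#'   `npv` (percentages), `agreement`, `kappa` for each arm (suffixed with
#'   the arm name), and the pooled `nri`.
#' @export
coef.edema_study <- function(object, ...) {
  out <- numeric(0)
  for (arm in names(object$arms)) {
    a <- object$arms[[arm]]
    m <- stats::setNames(a$metrics$estimate,
                         paste(a$metrics$metric, arm, sep = "."))
    out <- c(out, m,
             stats::setNames(c(a$agreement, a$kappa),
                             paste(c("agreement", "kappa"), arm, sep = ".")))
  }
  c(out, nri = object$nri$nri)
}

#' Confidence intervals of a reader-study fit
#'
#' @param object An [edema_study()] fit.
#' @param parm Optional character vector selecting rows by name.
#' @param level Ignored; intervals are computed at the level fixed when the
#'   study was fitted (changing it post hoc would silently mix levels with
#'   the stored NRI interval).
#' @param ... Unused.
#' @return Matrix with columns `lower`, `upper`; one row per diagnostic
#'   metric and arm plus the pooled NRI.  Rows for undefined metrics are
#'   `NA`.
#' @export
confint.edema_study <- function(object, parm = NULL, level = NULL, ...) {
  rows <- list()
  for (arm in names(object$arms)) {
    m <- object$arms[[arm]]$metrics
    for (i in seq_len(nrow(m)))
      rows[[paste(m$metric[i], arm, sep = ".")]] <- c(m$lower[i], m$upper[i])
  }
  rows[["nri"]] <- unname(object$nri$ci)
  out <- do.call(rbind, rows)
  colnames(out) <- c("lower", "upper")
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Plot per-reader operating points of both arms
#'
#' Draws each reader's (1 - specificity, sensitivity) under the old arm and
#' an arrow to the same reader's point under the new arm, visualising the
#' paired shift in operating characteristics that the NRI summarises.
#'
#' @param x An [edema_study()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.edema_study <- function(x, ...) {
  arms <- names(x$arms)
  pr_new <- x$arms[[1]]$per_reader
  pr_old <- x$arms[[2]]$per_reader
  sens_new <- pr_new$correct_edema / pr_new$n_edema
  spec_new <- pr_new$correct_no_edema / pr_new$n_no_edema
  sens_old <- pr_old$correct_edema / pr_old$n_edema
  spec_old <- pr_old$correct_no_edema / pr_old$n_no_edema
  graphics::plot(1 - spec_old, sens_old, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 pch = 1, main = "Per-reader operating points", ...)
  graphics::points(1 - spec_new, sens_new, pch = 16)
  keep <- (spec_old != spec_new) | (sens_old != sens_new)
  if (any(keep))
    graphics::arrows(1 - spec_old[keep], sens_old[keep],
                     1 - spec_new[keep], sens_new[keep],
                     length = 0.08, col = "grey40")
  graphics::abline(0, 1, lty = 3, col = "grey70")
  graphics::legend("bottomright", pch = c(1, 16), bty = "n",
                   legend = c(arms[2], arms[1]))
  invisible(x)
}
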