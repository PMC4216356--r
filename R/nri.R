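#' Net reclassification index for paired binary calls
#'
#' Quantifies the improvement of a new binary classifier over an old one on
#' paired readings against a binary reference.  Among event readings (true
#' edema), reclassifications from `no_edema` to `edema` count up and the
#' reverse counts down; among nonevent readings the directions are
#' mirrored.  The point estimate
#' `NRI = (up_ev - down_ev)/n_ev + (down_ne - up_ne)/n_ne`
#' is algebraically identical to the change in sensitivity plus the change
#' in specificity on the proportion scale.  The standard error uses the
#' asymptotic variance of the two paired-difference proportions,
#' `var = (p_up,ev + p_down,ev - (p_up,ev - p_down,ev)^2)/n_ev + <nonevent term>`,
#' with a normal-approximation two-sided p-value and Wald interval.  When
#' nothing is reclassified the standard error is zero and the p-value is
#' reported as `NA`.
#'
#' @param calls_old,calls_new Readers x cases call matrices on identical
#'   readers and cases (paired readings).
#' @param reference An [reference_standard()]; borderline cases are
#'   excluded before counting.
#' @param scope `"pooled"` (all readings together) or `"per_reader"`.
#' @param level Confidence level for the Wald interval.
#' @return For `scope = "pooled"` an object of class `nri_result`: list
#'   with `nri`, `up_events`, `down_events`, `up_nonevents`,
#'   `down_nonevents`, `n_events`, `n_nonevents`, `se`, `ci`, `p_value`.
#'   For `scope = "per_reader"` a named list of such objects, one per
#'   reader.
#' @export
binary_nri <- function(calls_old, calls_new, reference,
                       scope = c("pooled", "per_reader"), level = 0.95) {
  scope <- match.arg(scope)
  check_call_matrix(calls_old, "calls_old")
  check_call_matrix(calls_new, "calls_new")
  if (!identical(dimnames(calls_old), dimnames(calls_new)))
    abort_pairing("old and new call matrices must share readers and cases")
  old <- exclude_borderline(calls_old, reference)
  new <- exclude_borderline(calls_new, reference)
  if (scope == "pooled")
    return(nri_one(old$calls, new$calls, old$status, level))
  out <- lapply(rownames(calls_old), function(r)
    nri_one(old$calls[r, , drop = FALSE], new$calls[r, , drop = FALSE],
            old$status, level))
  stats::setNames(out, rownames(calls_old))
}

nri_one <- function(old, new, status, level) {
  truth <- matrix(status, nrow(old), ncol(old), byrow = TRUE)
  ev <- truth == "edema"
  n_ev <- sum(ev); n_ne <- sum(!ev)
  if (n_ev == 0 || n_ne == 0)
    abort_input("NRI needs at least one event and one nonevent reading")
  up <- old == "no_edema" & new == "edema"
  down <- old == "edema" & new == "no_edema"
  up_ev <- sum(up & ev);   down_ev <- sum(down & ev)
  up_ne <- sum(up & !ev);  down_ne <- sum(down & !ev)
  p_up_ev <- up_ev / n_ev; p_down_ev <- down_ev / n_ev
  p_up_ne <- up_ne / n_ne; p_down_ne <- down_ne / n_ne
  nri <- (p_up_ev - p_down_ev) + (p_down_ne - p_up_ne)
  v <- (p_up_ev + p_down_ev - (p_up_ev - p_down_ev)^2) / n_ev +
       (p_up_ne + p_down_ne - (p_up_ne - p_down_ne)^2) / n_ne
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    nri = nri,
    up_events = up_ev, down_events = down_ev,
    up_nonevents = up_ne, down_nonevents = down_ne,
    n_events = n_ev, n_nonevents = n_ne,
    se = se,
    ci = c(lower = nri - z * se, upper = nri + z * se),
    p_value = if (se > 0) 2 * stats::pnorm(-abs(nri / se)) else NA_real_,
    level = level
  ), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI %.3f  (se %.4f, %.0f%% CI %.3f - %.3f, p %s)\n",
              x$nri, x$se, 100 * x$level, x$ci[["lower"]], x$ci[["upper"]],
              if (is.na(x$p_value)) "NA (no reclassification)"
              else format.pval(x$p_value, digits = 3)))
  cat(sprintf("  events:    up %d / down %d of %d readings\n",
              x$up_events, x$down_events, x$n_events))
  cat(sprintf("  nonevents: up %d / down %d of %d readings\n",
              x$up_nonevents, x$down_nonevents, x$n_nonevents))
  invisible(x)
}
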