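#' Classify an extravascular lung water value
#'
#' PiCCO-derived EVLW in mL/kg is the reference standard for pulmonary
#' edema: values of 8 or below indicate no edema, 15 or above indicate
#' edema, and the band 9-14 is borderline and is excluded from accuracy
#' computations.  Non-integer values are rounded half-up to the nearest
#' integer before banding, matching the integer reporting of the device.
#'
#' @param evlw Numeric vector of EVLW values in mL/kg; must be positive.
#' @return Character vector: `"no_edema"`, `"borderline"` or `"edema"`.
#' @examples
#' classify_evlw(c(7, 12, 21))  # no_edema borderline edema
#' @export
classify_evlw <- function(evlw) {
  if (any(!is.finite(evlw)) || any(evlw <= 0))
    abort_input("EVLW values must be positive and finite")
  v <- floor(evlw + 0.5)  # half-up, not banker's rounding
  ifelse(v <= 8, "no_edema", ifelse(v >= 15, "edema", "borderline"))
}

#' Build a reference standard from case-level EVLW values
#'
#' @param cases Data frame with columns `case_id` and `evlw` (mL/kg).
#' @return Data frame of class `evlw_reference` with columns `case_id`,
#'   `evlw`, `status` (from [classify_evlw()]).  Borderline cases are kept
#'   and flagged by their status; evaluation functions exclude them.
#' @export
reference_standard <- function(cases) {
  if (!all(c("case_id", "evlw") %in% names(cases)))
    abort_validation("reference must have columns case_id, evlw")
  if (nrow(cases) == 0) abort_input("empty reference table")
  if (anyDuplicated(cases$case_id))
    abort_validation(sprintf("duplicate case ids in reference: %s",
      paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", ")))
  out <- data.frame(case_id = as.character(cases$case_id),
                    evlw = as.numeric(cases$evlw),
                    stringsAsFactors = FALSE)
  out$status <- classify_evlw(out$evlw)
  class(out) <- c("evlw_reference", "data.frame")
  out
}

# status lookup for a set of case ids, with pairing check
ref_status <- function(reference, case_ids) {
  idx <- match(case_ids, reference$case_id)
  if (anyNA(idx))
    abort_pairing(sprintf("cases missing from the reference standard: %s",
                          paste(case_ids[is.na(idx)], collapse = ", ")))
  reference$status[idx]
}
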