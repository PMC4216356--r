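#' Build a readers x cases call matrix
#'
#' The binary calls of a reader study are stored as a character matrix with
#' one row per reader and one column per case; entries are `"edema"` or
#' `"no_edema"`.  Row and column names carry the reader and case ids.
#'
#' @param calls Long data frame with columns `reader_id`, `case_id`, `call`,
#'   one row per reading; every reader must call every case exactly once.
#' @return The call matrix.
#' @export
as_call_matrix <- function(calls) {
  need <- c("reader_id", "case_id", "call")
  if (!all(need %in% names(calls)))
    abort_validation(sprintf("calls must have columns %s",
                             paste(need, collapse = ", ")))
  if (nrow(calls) == 0) abort_input("empty calls table")
  bad <- setdiff(unique(calls$call), c("edema", "no_edema"))
  if (length(bad))
    abort_validation(sprintf("invalid call values: %s",
                             paste(bad, collapse = ", ")))
  readers <- unique(as.character(calls$reader_id))
  cases <- unique(as.character(calls$case_id))
  m <- matrix(NA_character_, length(readers), length(cases),
              dimnames = list(readers, cases))
  idx <- cbind(match(calls$reader_id, readers), match(calls$case_id, cases))
  if (anyDuplicated(idx))
    abort_validation("duplicate (reader, case) readings in calls")
  m[idx] <- calls$call
  if (anyNA(m))
    abort_validation("incomplete call matrix: every reader must call every case")
  m
}

check_call_matrix <- function(m, what = "calls") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    abort_validation(sprintf("%s must be a readers x cases matrix with dimnames",
                             what))
  if (anyNA(m) || !all(m %in% c("edema", "no_edema")))
    abort_validation(sprintf("%s contains missing or invalid entries", what))
  invisible(m)
}

# drop borderline cases; returns list(matrix, status) aligned on columns
exclude_borderline <- function(calls, reference) {
  status <- ref_status(reference, colnames(calls))
  keep <- status != "borderline"
  list(calls = calls[, keep, drop = FALSE], status = status[keep],
       excluded = colnames(calls)[!keep])
}
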