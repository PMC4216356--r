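#' Score one rating sheet against the rubric
#'
#' A rating sheet is one reader's severity grading of every indicator for a
#' single radiograph.  Per-item points are looked up with [item_points()],
#' summed, and the total classified with [classify_score()].
#'
#' @param levels Named integer vector: one severity level per indicator id
#'   of the rubric (0 = missing).  Every indicator must appear exactly once.
#' @param rubric An [edema_rubric()]; default the shipped rubric.
#' @return An object of class `score_result`: list with `per_item_points`
#'   (named integer vector), `total` (integer) and `classification`
#'   (`"edema"` or `"no_edema"`).
#' @examples
#' lv <- c(hilar_enlarged = 1, hilar_density = 0, hilar_blurred = 2,
#'         kerley_b = 1, micronoduli = 0, fissure_widening = 1,
#'         cuffs = 0, perihilar_haze = 1, diffuse_density = 0)
#' total_score(lv)
#' @export
total_score <- function(levels, rubric = edema_rubric()) {
  want <- names(rubric$indicators)
  got <- names(levels)
  if (is.null(got)) abort_validation("levels must be a named vector")
  missing <- setdiff(want, got)
  extra <- setdiff(got, want)
  if (length(missing) || length(extra) || anyDuplicated(got))
    abort_validation(sprintf(
      "rating sheet does not match rubric (missing: %s; unknown: %s; duplicated: %s)",
      paste(missing, collapse = ", ") %empty% "none",
      paste(extra, collapse = ", ") %empty% "none",
      paste(unique(got[duplicated(got)]), collapse = ", ") %empty% "none"))
  pts <- vapply(want, function(id) item_points(rubric, id, levels[[id]]),
                integer(1))
  tot <- sum(pts)
  structure(list(per_item_points = pts, total = tot,
                 classification = classify_score(tot, rubric$threshold)),
            class = "score_result")
}

`%empty%` <- function(x, y) if (nzchar(x)) x else y

#' Classify a total score against the decision threshold
#'
#' Totals strictly greater than the threshold indicate pulmonary edema;
#' totals less than or equal to it indicate no pulmonary edema.  The
#' boundary is inclusive on the no-edema side: a total equal to the
#' threshold is `"no_edema"`.
#'
#' @param total Non-negative integer total score (vectorised).
#' @param threshold Integer decision threshold (default 15).
#' @return Character vector, `"edema"` or `"no_edema"`.
#' @examples
#' classify_score(c(15, 16, 24))  # no_edema edema edema
#' @export
classify_score <- function(total, threshold = 15L) {
  if (any(total < 0)) abort_input("total score cannot be negative")
  ifelse(total > threshold, "edema", "no_edema")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("Total score %d => %s\n", x$total, x$classification))
  pp <- x$per_item_points[x$per_item_points > 0]
  if (length(pp))
    cat("  ", paste(sprintf("%s=%d", names(pp), pp), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Score a long-format table of ratings
#'
#' @param ratings Data frame with columns `case_id`, `reader_id`,
#'   `indicator`, `level` — one row per (case, reader, indicator), as
#'   produced by [read_ratings()] or [simulate_ratings()].
#' @param rubric An [edema_rubric()].
#' @return Data frame with one row per (case, reader) sheet: `case_id`,
#'   `reader_id`, one `<indicator>` column of points per indicator, `total`
#'   and `classification`.
#' @export
score_ratings <- function(ratings, rubric = edema_rubric()) {
  need <- c("case_id", "reader_id", "indicator", "level")
  if (!all(need %in% names(ratings)))
    abort_validation(sprintf("ratings must have columns %s",
                             paste(need, collapse = ", ")))
  if (nrow(ratings) == 0) abort_input("empty ratings table")
  key <- interaction(ratings$case_id, ratings$reader_id, drop = TRUE,
                     lex.order = TRUE)
  out <- lapply(split(ratings, key), function(sh) {
    if (anyDuplicated(sh$indicator))
      abort_validation(sprintf(
        "duplicate indicator rows for case '%s', reader '%s': %s",
        sh$case_id[1], sh$reader_id[1],
        paste(unique(sh$indicator[duplicated(sh$indicator)]), collapse = ", ")))
    lv <- stats::setNames(as.integer(sh$level), sh$indicator)
    res <- total_score(lv, rubric)
    c(list(case_id = sh$case_id[1], reader_id = sh$reader_id[1]),
      as.list(res$per_item_points),
      list(total = res$total, classification = res$classification))
  })
  out <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Derive a binary call matrix from scored sheets
#'
#' @param scored Output of [score_ratings()].
#' @return A readers x cases character matrix of `"edema"` / `"no_edema"`
#'   calls (see [as_call_matrix()] for the layout contract).
#' @export
calls_from_scores <- function(scored) {
  as_call_matrix(data.frame(reader_id = scored$reader_id,
                            case_id = scored$case_id,
                            call = scored$classification,
                            stringsAsFactors = FALSE))
}
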