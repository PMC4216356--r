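#' Read and write rating sheets, call matrices and reference standards
#'
#' All files are plain comma-separated UTF-8 with a header row and no
#' quoting.  Schemas: ratings `case_id,reader_id,indicator,level`; calls
#' `reader_id,case_id,call` with call in `{edema, no_edema}`; reference
#' `case_id,evlw`.
#'
#' @param path File path.
#' @param rubric Rubric the ratings must validate against.
#' @param strict If `TRUE` (default) duplicate `(case, reader, indicator)`
#'   rows are an error; if `FALSE` the first occurrence wins.
#' @return `read_ratings()`: a validated long data frame of ratings (every
#'   sheet complete against the rubric).  `read_calls()`: a readers x
#'   cases call matrix.  `read_reference()`: an [reference_standard()]
#'   with borderline cases flagged by their status, not dropped.
#' @name study_io
NULL

read_csv_checked <- function(path, columns, what) {
  if (!file.exists(path)) abort_io(sprintf("%s file not found: %s", what, path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) abort_io(sprintf("cannot parse %s file %s: %s",
                                         what, path, conditionMessage(e))))
  if (!identical(sort(names(df)), sort(columns)))
    abort_validation(sprintf("%s file %s must have header %s (got: %s)",
                             what, path, paste(columns, collapse = ","),
                             paste(names(df), collapse = ",")))
  if (nrow(df) == 0)
    abort_input(sprintf("%s file %s contains no rows", what, path))
  df[columns]
}

#' @rdname study_io
#' @export
read_ratings <- function(path, rubric = edema_rubric(), strict = TRUE) {
  df <- read_csv_checked(path, c("case_id", "reader_id", "indicator", "level"),
                         "ratings")
  lvl <- suppressWarnings(as.integer(df$level))
  if (anyNA(lvl))
    abort_validation(sprintf("non-integer level at line(s) %s of %s",
                             paste(which(is.na(lvl)) + 1L, collapse = ", "),
                             path))
  df$level <- lvl
  unknown <- setdiff(unique(df$indicator), names(rubric$indicators))
  if (length(unknown))
    abort_validation(sprintf("unknown indicator(s) in %s: %s", path,
                             paste(unknown, collapse = ", ")))
  key <- paste(df$case_id, df$reader_id, df$indicator, sep = "\r")
  if (anyDuplicated(key)) {
    if (strict)
      abort_validation(sprintf("duplicate rating rows at line(s) %s of %s",
                               paste(which(duplicated(key)) + 1L,
                                     collapse = ", "), path))
    df <- df[!duplicated(key), ]
  }
  # completeness: score_ratings() validates each sheet against the rubric
  invisible(score_ratings(df, rubric))
  df
}

#' @rdname study_io
#' @export
read_calls <- function(path) {
  df <- read_csv_checked(path, c("reader_id", "case_id", "call"), "calls")
  as_call_matrix(df)
}

#' @rdname study_io
#' @export
read_reference <- function(path) {
  df <- read_csv_checked(path, c("case_id", "evlw"), "reference")
  evlw <- suppressWarnings(as.numeric(df$evlw))
  if (anyNA(evlw))
    abort_validation(sprintf("non-numeric evlw at line(s) %s of %s",
                             paste(which(is.na(evlw)) + 1L, collapse = ", "),
                             path))
  reference_standard(data.frame(case_id = df$case_id, evlw = evlw,
                                stringsAsFactors = FALSE))
}

#' @rdname study_io
#' @param ratings,calls,reference Objects to write (long ratings data
#'   frame, call matrix, reference standard).
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings[c("case_id", "reader_id", "indicator", "level")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
write_calls <- function(calls, path) {
  check_call_matrix(calls)
  long <- data.frame(
    reader_id = rep(rownames(calls), times = ncol(calls)),
    case_id = rep(colnames(calls), each = nrow(calls)),
    call = as.vector(calls), stringsAsFactors = FALSE)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
write_reference <- function(reference, path) {
  utils::write.csv(reference[c("case_id", "evlw")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# canonical, fully ordered list form of an edema_study (JSON surface)
as_report_list <- function(study) {
  arm_list <- function(a) {
    m <- a$metrics
    list(
      confusion = list(tp = a$counts$tp, fp = a$counts$fp,
                       tn = a$counts$tn, fn = a$counts$fn),
      metrics = lapply(stats::setNames(seq_len(nrow(m)), m$metric), function(i)
        list(estimate = m$estimate[i], lower = m$lower[i], upper = m$upper[i],
             successes = m$successes[i], trials = m$trials[i],
             defined = m$defined[i])),
      agreement = list(p_overall = a$agreement, kappa_free = a$kappa,
                       n_categories = 2L),
      per_reader_correct = a$per_reader
    )
  }
  nri_list <- function(x) list(
    nri = x$nri, up_events = x$up_events, down_events = x$down_events,
    up_nonevents = x$up_nonevents, down_nonevents = x$down_nonevents,
    n_events = x$n_events, n_nonevents = x$n_nonevents, se = x$se,
    ci = list(lower = x$ci[["lower"]], upper = x$ci[["upper"]]),
    p_value = x$p_value)
  list(
    readers = study$readers,
    cases = study$cases,
    excluded_borderline_cases = study$excluded_cases,
    arms = lapply(study$arms, arm_list),
    nri_pooled = nri_list(study$nri),
    nri_per_reader = lapply(study$nri_per_reader, nri_list),
    provenance = study$provenance
  )
}

#' Serialize a study report
#'
#' Writes an [edema_study()] fit either as JSON (full precision, fixed
#' field order, byte-stable across repeated calls) or as a short
#' tab-separated summary with display rounding (percentages and kappa/NRI
#' to two decimals).
#'
#' @param study An [edema_study()] fit.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
emit_report <- function(study, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  rep <- as_report_list(study)
  ok <- tryCatch({
    if (format == "json") {
      jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    } else {
      lines <- c("arm\tmeasure\tvalue")
      for (arm in names(rep$arms)) {
        a <- rep$arms[[arm]]
        for (m in names(a$metrics)) {
          v <- a$metrics[[m]]
          lines <- c(lines, sprintf("%s\t%s\t%s", arm, m,
            if (isTRUE(v$defined)) sprintf("%.2f", v$estimate) else "undefined"))
        }
        lines <- c(lines,
                   sprintf("%s\tagreement\t%.2f", arm, a$agreement$p_overall),
                   sprintf("%s\tkappa_free\t%.2f", arm, a$agreement$kappa_free))
      }
      lines <- c(lines, sprintf("pooled\tnri\t%.2f", rep$nri_pooled$nri))
      writeLines(lines, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write report to %s: %s", path,
                     conditionMessage(ok)))
  invisible(path)
}

#' Read back a JSON study report
#'
#' @param path Path written by [emit_report()] with `format = "json"`.
#' @return The report as a plain nested list (same shape as the JSON).
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("report file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
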