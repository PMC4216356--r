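#' The default pulmonary-edema scoring rubric
#'
#' Nine radiographic indicators of pulmonary edema are graded on ordinal
#' severity scales and mapped to weighted points.  Three indicators describe
#' the hilar vessels (enlarged, increased in density, blurred); the others
#' are Kerley B lines, micronoduli, widening of the interlobular fissure,
#' peribronchial/perivascular cuffs, extensive perihilar haze and a diffuse
#' increase in density.  Kerley B lines and micronoduli use a three-point
#' scale (missing / lower / higher severity); all other indicators use a
#' four-point scale (missing / mild / moderate / severe).  Level 0
#' ("missing") always scores zero points.  The weights reflect how
#' specifically each finding represents extravascular lung water: enlarged
#' hilar vessels top out at 3 points, perihilar haze and diffuse density at
#' 15.  The maximum attainable total is 88 and totals strictly greater than
#' the threshold (default 15) classify the radiograph as pulmonary edema.
#'
#' @param threshold Decision threshold on the total score; totals strictly
#'   above it are classified as edema.  Must lie strictly between 0 and the
#'   maximum attainable total.
#' @return An object of class `edema_rubric`: a list with elements
#'   `indicators` (a named list; each entry has `id`, `points` — the point
#'   value per level, index 1 = missing — and `labels`) and `threshold`.
#' @examples
#' r <- edema_rubric()
#' r$indicators$hilar_blurred$points   # 0 3 6 9
#' rubric_max(r)                       # 88
#' @seealso [item_points()], [total_score()], [read_rubric()]
#' @export
edema_rubric <- function(threshold = 15L) {
  ind <- function(id, points, labels) list(id = id, points = as.integer(points),
                                           labels = labels)
  lab4 <- c("missing", "mild", "moderate", "severe")
  lab3 <- c("missing", "lower", "higher")
  indicators <- list(
    ind("hilar_enlarged",   c(0, 1, 2, 3),    lab4),
    ind("hilar_density",    c(0, 2, 4, 6),    lab4),
    ind("hilar_blurred",    c(0, 3, 6, 9),    lab4),
    ind("kerley_b",         c(0, 4, 8),       lab3),
    ind("micronoduli",      c(0, 4, 8),       lab3),
    ind("fissure_widening", c(0, 4, 8, 12),   lab4),
    ind("cuffs",            c(0, 4, 8, 12),   lab4),
    ind("perihilar_haze",   c(0, 5, 10, 15),  lab4),
    ind("diffuse_density",  c(0, 5, 10, 15),  lab4)
  )
  names(indicators) <- vapply(indicators, `[[`, "", "id")
  new_rubric(indicators, threshold)
}

new_rubric <- function(indicators, threshold) {
  r <- structure(list(indicators = indicators, threshold = as.integer(threshold)),
                 class = "edema_rubric")
  validate_rubric(r)
  r
}

validate_rubric <- function(rubric) {
  if (!is.list(rubric$indicators) || length(rubric$indicators) == 0)
    abort_validation("rubric has no indicators")
  for (ind in rubric$indicators) {
    p <- ind$points
    if (p[1] != 0)
      abort_validation(sprintf("indicator '%s': the missing level must score 0",
                               ind$id))
    if (any(diff(p) <= 0))
      abort_validation(sprintf(
        "indicator '%s': points must be strictly increasing across levels",
        ind$id))
    if (length(ind$labels) != length(p))
      abort_validation(sprintf("indicator '%s': %d labels for %d levels",
                               ind$id, length(ind$labels), length(p)))
  }
  mx <- rubric_max(rubric)
  if (rubric$threshold <= 0 || rubric$threshold >= mx)
    abort_validation(sprintf(
      "threshold %d must lie strictly between 0 and the maximum total %d",
      rubric$threshold, mx))
  invisible(rubric)
}

#' Maximum attainable total score of a rubric
#'
#' @param rubric An [edema_rubric()].
#' @return Integer: the sum over indicators of the top point value (88 for
#'   the default rubric).
#' @export
rubric_max <- function(rubric) {
  sum(vapply(rubric$indicators, function(i) max(i$points), integer(1)))
}

#' Points awarded for one indicator at one severity level
#'
#' @param rubric An [edema_rubric()].
#' @param indicator Indicator id, e.g. `"perihilar_haze"`.
#' @param level Integer severity level index; 0 is "missing" and always
#'   scores 0 points.
#' @return Integer points.
#' @examples
#' item_points(edema_rubric(), "perihilar_haze", 3)  # 15
#' @export
item_points <- function(rubric, indicator, level) {
  ind <- rubric$indicators[[indicator]]
  if (is.null(ind))
    abort_validation(sprintf("unknown indicator '%s'", indicator))
  level <- as.integer(level)
  if (is.na(level) || level < 0 || level >= length(ind$points))
    abort_validation(sprintf(
      "indicator '%s': level %s out of range (must be 0..%d)",
      indicator, as.character(level), length(ind$points) - 1L))
  ind$points[level + 1L]
}

#' Checksum identifying a rubric configuration
#'
#' MD5 digest of the canonical textual form of the rubric (indicator ids,
#' point vectors, threshold), used to stamp reports so scores can be traced
#' to the exact weight configuration that produced them.
#'
#' @param rubric An [edema_rubric()].
#' @return A 32-character hex string.
#' @export
rubric_checksum <- function(rubric) {
  canon <- paste(
    vapply(rubric$indicators,
           function(i) paste0(i$id, ":", paste(i$points, collapse = ",")),
           character(1)),
    collapse = ";")
  canon <- paste0(canon, "|threshold=", rubric$threshold)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

#' Read a rubric from a YAML configuration file
#'
#' The file holds one mapping per indicator under `indicators` (keys are
#' indicator ids, values the point vector with leading 0 for "missing") and
#' a `threshold`.  Intended for sensitivity-to-weights experiments; the
#' shipped default ([edema_rubric()]) is the validated clinical rubric.
#'
#' @param path Path to a YAML file.
#' @return An `edema_rubric`.
#' @export
read_rubric <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("rubric file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators) || is.null(cfg$threshold))
    abort_validation("rubric YAML must contain 'indicators' and 'threshold'")
  def <- edema_rubric()
  indicators <- lapply(names(cfg$indicators), function(id) {
    pts <- as.integer(cfg$indicators[[id]])
    labels <- if (!is.null(def$indicators[[id]]) &&
                  length(def$indicators[[id]]$labels) == length(pts))
      def$indicators[[id]]$labels
    else c("missing", paste0("level", seq_len(length(pts) - 1L)))
    list(id = id, points = pts, labels = labels)
  })
  names(indicators) <- names(cfg$indicators)
  new_rubric(indicators, cfg$threshold)
}

#' @export
print.edema_rubric <- function(x, ...) {
  cat("Pulmonary-edema scoring rubric\n")
  cat(sprintf("  %d indicators, threshold > %d => edema, maximum total %d\n\n",
              length(x$indicators), x$threshold, rubric_max(x)))
  for (ind in x$indicators) {
    cat(sprintf("  %-17s %s\n", ind$id,
                paste(sprintf("%s=%d", ind$labels, ind$points), collapse = "  ")))
  }
  invisible(x)
}
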