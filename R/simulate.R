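#' Simulate an EVLW-defined patient cohort
#'
#' Emulates the two-group case-selection design of a bedside-radiograph
#' reader study: patients with EVLW of at most 8 mL/kg (no edema) and
#' patients with EVLW of at least 15 mL/kg (edema), optionally plus
#' borderline patients (9-14 mL/kg).  Integer EVLW values are drawn
#' uniformly within each group's range, matching the integer reporting of
#' the thermodilution device.
#'
#' @param n_edema,n_no_edema,n_borderline Group sizes (default 10 / 10 / 0,
#'   the classic two-arm design).
#' @param evlw_ranges Named list of `c(low, high)` integer ranges per group;
#'   defaults `no_edema = 4:8`, `edema = 15:21`, `borderline = 9:14`.
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return An [reference_standard()] data frame (`case_id`, `evlw`,
#'   `status`), cases ordered edema first.
#' @examples
#' simulate_cohort(n_edema = 3, n_no_edema = 3, seed = 1)
#' @export
simulate_cohort <- function(n_edema = 10, n_no_edema = 10, n_borderline = 0,
                            evlw_ranges = list(no_edema = c(4, 8),
                                               edema = c(15, 21),
                                               borderline = c(9, 14)),
                            seed = NULL) {
  n <- c(edema = n_edema, no_edema = n_no_edema, borderline = n_borderline)
  if (any(n < 0)) abort_input("group counts must be non-negative")
  if (sum(n) == 0) abort_input("empty cohort")
  for (g in names(evlw_ranges)) {
    rng <- evlw_ranges[[g]]
    if (!all(classify_evlw(rng) == g))
      abort_input(sprintf(
        "evlw range for group '%s' leaves the group's EVLW band", g))
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(g, k) {
    rng <- evlw_ranges[[g]]
    sample(seq(rng[1], rng[2]), k, replace = TRUE)
  }
  evlw <- c(draw("edema", n[["edema"]]),
            draw("no_edema", n[["no_edema"]]),
            if (n[["borderline"]] > 0) draw("borderline", n[["borderline"]]))
  reference_standard(data.frame(
    case_id = sprintf("case%02d", seq_along(evlw)),
    evlw = evlw, stringsAsFactors = FALSE))
}

#' Per-indicator severity distributions conditional on edema status
#'
#' The generative link between true edema status and radiographic findings:
#' for each rubric indicator, a probability vector over its severity levels
#' given that the case truly has edema, and another given that it does not.
#' Two presets ship:
#' \describe{
#'   \item{`"separable"`}{degenerate — edema cases show every indicator at
#'     its top level, non-edema cases show nothing; useful for exercising
#'     the pipeline where the score arm must be perfect.}
#'   \item{`"paper_like"`}{calibrated so that the latent total-score
#'     distribution crosses the threshold with probability about 0.77 for
#'     edema cases and essentially never (about 0.0006) for non-edema
#'     cases, i.e. score-based reading operates near 77% sensitivity at
#'     100% specificity.}
#' }
#' No biological claim is attached to either preset; they are study-design
#' emulators.  Borderline cases, if simulated, draw from a 50/50 mixture of
#' the two conditionals.
#'
#' @param preset `"paper_like"` (default) or `"separable"`.
#' @param custom Optional named list overriding the preset: per indicator
#'   id, a list with elements `edema` and `no_edema`, each a probability
#'   vector over that indicator's levels.
#' @param rubric Rubric whose scales the model must match.
#' @return Object of class `severity_model`: named list per indicator with
#'   `edema` and `no_edema` probability vectors.
#' @export
severity_model <- function(preset = c("paper_like", "separable"),
                           custom = NULL, rubric = edema_rubric()) {
  preset <- match.arg(preset)
  mk <- function(ind) {
    nlev <- length(ind$points)
    if (preset == "separable") {
      ed <- c(rep(0, nlev - 1), 1)
      ne <- c(1, rep(0, nlev - 1))
    } else if (nlev == 4) {
      ed <- c(0.51, 0.28, 0.13, 0.08)
      ne <- c(0.93, 0.07, 0.00, 0.00)
    } else {
      ed <- c(0.55, 0.32, 0.13)
      ne <- c(0.94, 0.06, 0.00)
    }
    list(edema = ed, no_edema = ne)
  }
  model <- lapply(rubric$indicators, mk)
  if (!is.null(custom)) model[names(custom)] <- custom
  validate_severity_model(model, rubric)
  structure(model, class = "severity_model")
}

validate_severity_model <- function(model, rubric = edema_rubric()) {
  ids <- names(rubric$indicators)
  if (!setequal(names(model), ids))
    abort_validation("severity model must cover exactly the rubric's indicators")
  for (id in ids) {
    nlev <- length(rubric$indicators[[id]]$points)
    for (grp in c("edema", "no_edema")) {
      p <- model[[id]][[grp]]
      if (length(p) != nlev)
        abort_validation(sprintf(
          "severity model for '%s' (%s): %d probabilities for %d levels",
          id, grp, length(p), nlev))
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        abort_validation(sprintf(
          "severity model for '%s' (%s) is not a probability vector", id, grp))
    }
  }
  invisible(model)
}

#' Reader profiles for the synthetic study
#'
#' @param n_readers Number of readers.
#' @param rating_noise Probability that a reader mis-grades any single
#'   indicator by one severity level (direction symmetric, clamped to the
#'   valid range).
#' @param standard_sens,standard_spec Operating point of each reader's
#'   unaided (standard) binary call: the probability of calling edema on a
#'   true edema case, and of calling no-edema on a true non-edema case.
#'   Defaults are the pooled operating point of experienced radiologists
#'   reading bedside radiographs unaided (sensitivity 0.5714, specificity
#'   0.90).
#' @return Data frame of class `reader_profiles` with one row per reader.
#' @export
reader_profiles <- function(n_readers = 7, rating_noise = 0.05,
                            standard_sens = 0.5714, standard_spec = 0.90) {
  if (n_readers < 1) abort_input("need at least one reader")
  p <- c(rating_noise, standard_sens, standard_spec)
  if (any(p < 0 | p > 1)) abort_input("probabilities must lie in [0, 1]")
  out <- data.frame(reader_id = sprintf("reader%d", seq_len(n_readers)),
                    rating_noise = rating_noise,
                    standard_sens = standard_sens,
                    standard_spec = standard_spec,
                    stringsAsFactors = FALSE)
  class(out) <- c("reader_profiles", "data.frame")
  out
}

#' Simulate per-reader rating sheets for a cohort
#'
#' For each case one latent severity level per indicator is drawn from the
#' severity model conditional on the case's true status; each reader then
#' observes the latent level, mis-graded by one level with probability
#' `rating_noise` (direction chosen at random, clamped to the indicator's
#' scale).  Borderline cases draw their latent profile from the edema
#' conditional with probability one half, otherwise from the non-edema
#' conditional.
#'
#' @param cohort An [reference_standard()], e.g. from [simulate_cohort()].
#' @param model A [severity_model()].
#' @param profiles A [reader_profiles()] data frame.
#' @param rubric The scoring rubric the sheets must validate against.
#' @param seed Optional integer seed.
#' @return Long data frame `case_id`, `reader_id`, `indicator`, `level` —
#'   one row per (case, reader, indicator), valid input for
#'   [score_ratings()].
#' @export
simulate_ratings <- function(cohort, model = severity_model(),
                             profiles = reader_profiles(),
                             rubric = edema_rubric(), seed = NULL) {
  validate_severity_model(model, rubric)
  if (!is.null(seed)) set.seed(seed)
  ids <- names(rubric$indicators)
  latent <- lapply(seq_len(nrow(cohort)), function(i) {
    st <- cohort$status[i]
    if (st == "borderline")
      st <- if (stats::runif(1) < 0.5) "edema" else "no_edema"
    vapply(ids, function(id) {
      p <- model[[id]][[st]]
      sample.int(length(p), 1, prob = p) - 1L
    }, integer(1))
  })
  rows <- vector("list", nrow(cohort) * nrow(profiles))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (r in seq_len(nrow(profiles))) {
      lv <- latent[[i]]
      noise <- profiles$rating_noise[r]
      if (noise > 0) {
        flip <- stats::runif(length(lv)) < noise
        if (any(flip)) {
          dir <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
          top <- vapply(ids[flip],
                        function(id) length(rubric$indicators[[id]]$points) - 1L,
                        integer(1))
          lv[flip] <- pmin(pmax(lv[flip] + dir, 0L), top)
        }
      }
      k <- k + 1L
      rows[[k]] <- data.frame(case_id = cohort$case_id[i],
                              reader_id = profiles$reader_id[r],
                              indicator = ids, level = unname(lv),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a complete synthetic two-arm reader study
#'
#' Ties the generator to the evaluation machinery: simulates rating sheets,
#' scores them to produce the score-based call matrix, draws each reader's
#' unaided standard calls from their configured operating point, and
#' evaluates both arms with [edema_study()].
#'
#' @param cohort An [reference_standard()], e.g. from [simulate_cohort()].
#' @param model,profiles,rubric As in [simulate_ratings()].
#' @param seed Integer seed governing all randomness of the run.
#' @param ci_method,level Passed to [edema_study()].
#' @return List with `ratings` (long data frame), `calls_score`,
#'   `calls_standard` (call matrices), `cohort`, and `study` (the
#'   [edema_study()] fit, with the seed recorded in its provenance block).
#' @examples
#' res <- run_virtual_study(simulate_cohort(seed = 7), seed = 7)
#' coef(res$study)["nri"]
#' @export
run_virtual_study <- function(cohort, model = severity_model(),
                              profiles = reader_profiles(),
                              rubric = edema_rubric(), seed = NULL,
                              ci_method = "clopper_pearson", level = 0.95) {
  force(cohort); force(model); force(profiles)  # promises may touch the RNG
  if (!is.null(seed)) set.seed(seed)
  ratings <- simulate_ratings(cohort, model, profiles, rubric, seed = NULL)
  scored <- score_ratings(ratings, rubric)
  calls_score <- calls_from_scores(scored)
  # unaided arm: Bernoulli draw at each reader's configured operating point;
  # borderline cases get a coin flip (they are excluded downstream anyway)
  calls_standard <- calls_score
  for (r in seq_len(nrow(profiles))) {
    rid <- profiles$reader_id[r]
    p_edema_call <- ifelse(cohort$status == "edema", profiles$standard_sens[r],
                    ifelse(cohort$status == "no_edema",
                           1 - profiles$standard_spec[r], 0.5))
    draw <- stats::runif(nrow(cohort)) < p_edema_call
    calls_standard[rid, cohort$case_id] <- ifelse(draw, "edema", "no_edema")
  }
  # keep reader/case ordering identical across arms
  calls_standard <- calls_standard[rownames(calls_score), colnames(calls_score),
                                   drop = FALSE]
  study <- edema_study(calls_score, calls_standard, cohort,
                       ci_method = ci_method, level = level)
  study$provenance$seed <- seed
  list(ratings = ratings, calls_score = calls_score,
       calls_standard = calls_standard, cohort = cohort, study = study)
}
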