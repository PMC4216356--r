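test_that("simulated cohorts respect group sizes, bands and determinism", {
  co <- simulate_cohort(n_edema = 10, n_no_edema = 10, seed = 61)
  expect_identical(nrow(co), 20L)
  expect_identical(sum(co$status == "edema"), 10L)
  expect_identical(sum(co$status == "no_edema"), 10L)
  expect_true(all(co$evlw[co$status == "edema"] %in% 15:21))
  expect_true(all(co$evlw[co$status == "no_edema"] %in% 4:8))
  expect_true(all(co$evlw == floor(co$evlw)))
  expect_identical(co, simulate_cohort(n_edema = 10, n_no_edema = 10, seed = 61))

  all_neg <- simulate_cohort(n_edema = 0, n_no_edema = 5, seed = 61)
  expect_true(all(all_neg$status == "no_edema"))
  withb <- simulate_cohort(4, 4, 3, seed = 62)
  expect_identical(sum(withb$status == "borderline"), 3L)
  expect_error(simulate_cohort(0, 0, 0), class = "edemascore_input_error")
  expect_error(simulate_cohort(5, 5, evlw_ranges = list(
    no_edema = c(4, 9), edema = c(15, 21), borderline = c(9, 14))),
    class = "edemascore_input_error")
})

test_that("severity models validate their probability vectors", {
  m <- severity_model("paper_like")
  r <- edema_rubric()
  for (id in names(r$indicators)) {
    for (grp in c("edema", "no_edema")) {
      p <- m[[id]][[grp]]
      expect_length(p, length(r$indicators[[id]]$points))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
  bad <- severity_model("separable")
  bad$kerley_b$edema <- c(0.5, 0.5)  # wrong length
  expect_error(validate_severity_model(bad),
               class = "edemascore_validation_error")
})

test_that("the separable model with zero noise is perfectly classified", {
  co <- simulate_cohort(5, 5, seed = 63)
  prof <- reader_profiles(n_readers = 3, rating_noise = 0)
  ratings <- simulate_ratings(co, severity_model("separable"), prof, seed = 63)
  scored <- score_ratings(ratings)
  expect_true(all(scored$total[scored$case_id %in%
                                 co$case_id[co$status == "edema"]] == 88L))
  expect_true(all(scored$total[scored$case_id %in%
                                 co$case_id[co$status == "no_edema"]] == 0L))
  # zero-noise readers all produce the identical sheet for a case
  per_case <- split(scored$total, scored$case_id)
  expect_true(all(vapply(per_case, function(x) length(unique(x)) == 1,
                         logical(1))))
  res <- run_virtual_study(co, severity_model("separable"), prof, seed = 63)
  cf <- coef(res$study)
  expect_equal(cf[["sensitivity.score_based"]], 100)
  expect_equal(cf[["specificity.score_based"]], 100)
})

test_that("simulated ratings are always valid rating sheets", {
  co <- simulate_cohort(4, 4, 2, seed = 64)
  ratings <- simulate_ratings(co, severity_model("paper_like"),
                              reader_profiles(4, rating_noise = 0.3),
                              seed = 64)
  expect_identical(nrow(ratings), 10L * 4L * 9L)
  expect_no_error(score_ratings(ratings))  # full per-sheet validation
  r <- edema_rubric()
  for (id in names(r$indicators)) {
    lv <- ratings$level[ratings$indicator == id]
    expect_true(all(lv >= 0 & lv < length(r$indicators[[id]]$points)))
  }
})

test_that("a full virtual study is reproducible and internally consistent", {
  co <- simulate_cohort(10, 10, seed = 65)
  a <- run_virtual_study(co, seed = 65)
  b <- run_virtual_study(co, seed = 65)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$calls_standard, b$calls_standard)
  expect_identical(coef(a$study), coef(b$study))
  # inline cohort generation must give the same study as a precomputed one
  c_inline <- run_virtual_study(simulate_cohort(10, 10, seed = 65), seed = 65)
  expect_identical(coef(c_inline$study), coef(a$study))
  expect_identical(a$study$provenance$seed, 65)
  # score arm derives from the scored sheets
  scored <- score_ratings(a$ratings)
  expect_identical(calls_from_scores(scored), a$calls_score)
})

test_that("standard-arm calls converge to the configured operating point", {
  co <- simulate_cohort(1000, 1000, seed = 66)
  prof <- reader_profiles(7, standard_sens = 0.57, standard_spec = 0.90)
  res <- run_virtual_study(co, profiles = prof, seed = 66)
  cf <- coef(res$study)
  expect_equal(cf[["sensitivity.standard"]], 57, tolerance = 0.04)
  expect_equal(cf[["specificity.standard"]], 90, tolerance = 0.02)
})
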