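test_that("pooled confusion counts reproduce the published reader tallies", {
  s <- example_reader_study()
  cc_score <- pooled_confusion(s$calls_score, s$reference)
  expect_identical(unlist(cc_score[c("tp", "fn", "tn", "fp")]),
                   c(tp = 54L, fn = 16L, tn = 70L, fp = 0L))
  cc_std <- pooled_confusion(s$calls_standard, s$reference)
  expect_identical(unlist(cc_std[c("tp", "fn", "tn", "fp")]),
                   c(tp = 40L, fn = 30L, tn = 63L, fp = 7L))
})

test_that("a perfect single reader yields a perfect confusion matrix", {
  ref <- balanced_reference(20)
  calls <- matrix(ifelse(ref$status == "edema", "edema", "no_edema"), 1,
                  dimnames = list("r1", ref$case_id))
  cc <- pooled_confusion(calls, ref)
  expect_identical(unlist(cc[c("tp", "fn", "tn", "fp")]),
                   c(tp = 10L, fn = 0L, tn = 10L, fp = 0L))
  m <- diagnostic_metrics(cc)
  expect_equal(m$estimate, rep(100, 4))
})

test_that("borderline cases are rejected by pooled_confusion and pairing is checked", {
  ref <- reference_standard(data.frame(case_id = c("a", "b", "c"),
                                       evlw = c(18, 6, 12)))
  calls <- matrix("edema", 2, 3, dimnames = list(c("r1", "r2"), c("a", "b", "c")))
  expect_error(pooled_confusion(calls, ref), class = "edemascore_input_error")
  calls2 <- matrix("edema", 2, 2, dimnames = list(c("r1", "r2"), c("a", "zz")))
  expect_error(pooled_confusion(calls2, ref),
               class = "edemascore_pairing_error")
})

test_that("diagnostic metrics match the published pooled percentages", {
  m <- diagnostic_metrics(confusion_counts(tp = 54, fp = 0, tn = 70, fn = 16))
  est <- stats::setNames(m$estimate, m$metric)
  expect_equal(est[["sensitivity"]], 100 * 54 / 70, tolerance = 1e-12)
  expect_equal(round(est[["sensitivity"]], 2), 77.14)
  expect_equal(est[["specificity"]], 100)
  expect_equal(est[["ppv"]], 100)
  expect_equal(round(est[["npv"]], 2), 81.40)

  m2 <- diagnostic_metrics(confusion_counts(tp = 40, fp = 7, tn = 63, fn = 30))
  est2 <- stats::setNames(m2$estimate, m2$metric)
  expect_equal(round(est2[["sensitivity"]], 2), 57.14)
  expect_equal(est2[["specificity"]], 90)
  expect_equal(round(est2[["ppv"]], 2), 85.11)
  expect_equal(round(est2[["npv"]], 2), 67.74)
})

test_that("point estimates always lie inside their confidence intervals", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:200, 4, replace = TRUE)
    cc <- confusion_counts(tp = sample(0:n[1], 1), fp = sample(0:n[2], 1),
                           tn = sample(0:n[3], 1), fn = sample(0:n[4], 1))
    if (cc$tp + cc$fn == 0 || cc$tn + cc$fp == 0) next
    for (method in c("clopper_pearson", "wilson")) {
      m <- diagnostic_metrics(cc, ci_method = method)
      ok <- m$defined
      expect_true(all(m$lower[ok] <= m$estimate[ok] + 1e-9))
      expect_true(all(m$upper[ok] >= m$estimate[ok] - 1e-9))
      expect_true(all(m$lower[ok] >= 0 & m$upper[ok] <= 100))
    }
  }
})

test_that("undefined predictive values are flagged, not coerced to 0 or 100", {
  # a reader calling everything negative has no positive calls: PPV undefined
  m <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 10, fn = 10))
  ppv <- m[m$metric == "ppv", ]
  expect_false(ppv$defined)
  expect_true(is.na(ppv$estimate))
  m2 <- diagnostic_metrics(confusion_counts(tp = 10, fp = 10, tn = 0, fn = 0))
  npv <- m2[m2$metric == "npv", ]
  expect_false(npv$defined)
  expect_error(diagnostic_metrics(confusion_counts(0, 5, 5, 0)),
               class = "edemascore_input_error")  # no event readings at all
})

test_that("Clopper-Pearson interval matches its closed forms and binom.test", {
  # x = n: lower bound has the closed form (alpha/2)^(1/n)
  ci <- proportion_ci(70, 70)
  expect_equal(ci[["lower"]], 100 * 0.025^(1 / 70), tolerance = 1e-10)
  expect_equal(ci[["upper"]], 100)
  # x = 0 mirrors it
  ci0 <- proportion_ci(0, 70)
  expect_equal(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 100 * (1 - 0.025^(1 / 70)), tolerance = 1e-10)
  # general case against the independent exact-test oracle
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:300, 1); x <- sample(0:n, 1)
    lvl <- sample(c(0.9, 0.95, 0.99), 1)
    got <- proportion_ci(x, n, "clopper_pearson", lvl)
    ref <- 100 * as.numeric(stats::binom.test(x, n, conf.level = lvl)$conf.int)
    expect_equal(unname(got), ref, tolerance = 1e-9)
  }
})

test_that("Wilson interval matches the score-test oracle", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:300, 1); x <- sample(0:n, 1)
    got <- proportion_ci(x, n, "wilson")
    ref <- 100 * as.numeric(suppressWarnings(
      stats::prop.test(x, n, correct = FALSE)$conf.int))
    expect_equal(unname(got), ref, tolerance = 1e-9)
  }
  expect_error(proportion_ci(1, 0), class = "edemascore_input_error")
  expect_error(proportion_ci(5, 3), class = "edemascore_input_error")
})
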