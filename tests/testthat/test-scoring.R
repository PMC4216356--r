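test_that("total_score matches the worked examples and the bounds", {
  r <- edema_rubric()
  ids <- names(r$indicators)
  all0 <- stats::setNames(rep(0L, 9), ids)
  res0 <- total_score(all0, r)
  expect_identical(res0$total, 0L)
  expect_identical(res0$classification, "no_edema")

  top <- vapply(r$indicators, function(i) length(i$points) - 1L, integer(1))
  res_max <- total_score(top, r)
  expect_identical(res_max$total, 88L)
  expect_identical(res_max$classification, "edema")

  # a radiograph totalling 24 points indicates edema, one totalling 4 does not
  s24 <- stats::setNames(c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 3L, 1L), ids)  # 3+15+5+1?
  s24["hilar_enlarged"] <- 1L
  expect_identical(total_score(s24, r)$total, 24L)
  expect_identical(total_score(s24, r)$classification, "edema")
  s4 <- stats::setNames(rep(0L, 9), ids); s4["kerley_b"] <- 1L
  expect_identical(total_score(s4, r)$total, 4L)
  expect_identical(total_score(s4, r)$classification, "no_edema")
})

test_that("classification threshold is strict and boundary-inclusive on no-edema", {
  expect_identical(classify_score(15, 15), "no_edema")
  expect_identical(classify_score(16, 15), "edema")
  expect_identical(unname(classify_score(c(0, 15, 16, 24, 88), 15)),
                   c("no_edema", "no_edema", "edema", "edema", "edema"))
  expect_error(classify_score(-1), class = "edemascore_input_error")
})

test_that("total_score rejects incomplete, extra or duplicated indicators", {
  r <- edema_rubric()
  ids <- names(r$indicators)
  lv <- stats::setNames(rep(0L, 9), ids)
  err <- tryCatch(total_score(lv[-4], r), condition = identity)
  expect_s3_class(err, "edemascore_validation_error")
  expect_match(conditionMessage(err), "kerley_b")
  expect_error(total_score(c(lv, bat_wing = 1L), r),
               class = "edemascore_validation_error")
  # order does not matter, only the id set
  expect_no_error(total_score(stats::setNames(rep(0L, 9), c(ids[-1], ids[1])), r))
  expect_error(total_score(unname(lv), r),
               class = "edemascore_validation_error")
})

test_that("random sheets agree with the brute-force oracle and stay in range", {
  set.seed(41)
  r <- edema_rubric()
  for (i in 1:200) {
    lv <- random_sheet()
    res <- total_score(lv, r)
    expect_identical(res$total, as.integer(oracle_total(lv)))
    expect_true(res$total >= 0 && res$total <= 88)
    expect_identical(res$total, as.integer(sum(res$per_item_points)))
    expect_identical(res$classification,
                     if (res$total > 15) "edema" else "no_edema")
  }
})

test_that("raising any single indicator level never decreases the total", {
  set.seed(42)
  r <- edema_rubric()
  for (i in 1:50) {
    lv <- random_sheet()
    base <- total_score(lv, r)$total
    for (id in names(lv)) {
      nlev <- length(r$indicators[[id]]$points)
      if (lv[[id]] + 1L < nlev) {
        up <- lv; up[[id]] <- up[[id]] + 1L
        expect_gt(total_score(up, r)$total, base - 1L)
      }
    }
  }
})

test_that("score_ratings scores long-format tables sheet by sheet", {
  set.seed(43)
  sheets <- list(a = random_sheet(), b = random_sheet())
  ratings <- do.call(rbind, lapply(names(sheets), function(cs)
    data.frame(case_id = cs, reader_id = "r1",
               indicator = names(sheets[[cs]]),
               level = unname(sheets[[cs]]))))
  out <- score_ratings(ratings)
  expect_identical(nrow(out), 2L)
  expect_identical(out$total[out$case_id == "a"],
                   as.integer(oracle_total(sheets$a)))
  expect_identical(out$total[out$case_id == "b"],
                   as.integer(oracle_total(sheets$b)))
  dup <- rbind(ratings, ratings[1, ])
  expect_error(score_ratings(dup), class = "edemascore_validation_error")
  expect_error(score_ratings(ratings[0, ]), class = "edemascore_input_error")
})
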