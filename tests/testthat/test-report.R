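test_that("full_report rejects empty or transition-free logs", {
  expect_error(full_report(searchcode:::empty_study_log()), "empty")
  expect_error(full_report(make_session_log("PubMed")), "no codable")
})

test_that("single-arm logs produce tables but skip between-arm tests", {
  log <- generate_study_log(behavior_spec("task", n_participants = 4L, seed = 2L))
  rep <- full_report(log)
  expect_false(rep$two_arm)
  expect_null(rep$blocks$profile$chisq)
  expect_true(all(is.na(rep$blocks$profile$cells$z)))
  expect_equal(rep$n_tests, 0L)
  txt <- searchcode:::render_report(rep)
  expect_true(any(grepl("single-arm", txt)))
})

test_that("two-arm reports carry per-table chi-square and per-row z tests", {
  rep <- paper_report()
  expect_true(rep$two_arm)
  expect_s3_class(rep$blocks$profile$chisq, "chisq_result")
  expect_equal(rep$blocks$profile$chisq$df, 2L)
  expect_equal(rep$blocks$query$chisq$df, 3L)
  expect_equal(rep$blocks$combo$chisq$df, 11L)
  expect_false(any(is.na(rep$blocks$combo$cells$z)))
  expect_gt(rep$n_tests, 0L)
})

test_that("report output files are byte-identical across runs", {
  rep <- paper_report()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(rep, d1)
  write_report(rep, d2)
  files <- c("table3.csv", "table4.csv", "table5.csv", "table6.csv",
             "table7.csv", "report.txt")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("p-value display follows the <.001 convention", {
  expect_equal(searchcode:::format_p(0.0004), "<.001")
  expect_equal(searchcode:::format_p(0.049), "= 0.049")
})
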