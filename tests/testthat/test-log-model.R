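test_that("a minimal well-formed log groups events into sessions", {
  log <- make_session_log(c("PubMed", "PubMed"))
  expect_s3_class(log, "study_log")
  s <- summarize_log(log)
  expect_equal(s$n_sessions, 1L)
  expect_equal(s$n_searches, 2L)
  expect_equal(s$n_transitions, 1L)
})

test_that("log validation rejects broken inputs", {
  base <- data.frame(participant_id = "p1", session_id = "s1",
                     arm = "resource", seq_index = 1:2, profile = "PubMed",
                     kw_disease = "asthma", kw_drug = "", kw_symptom = "",
                     kw_other = "", stringsAsFactors = FALSE)
  dup <- base; dup$seq_index <- c(1L, 1L)
  expect_error(study_log(dup), "duplicate seq_index")
  gap <- base; gap$seq_index <- c(1L, 3L)
  expect_error(study_log(gap), "not contiguous")
  badarm <- base; badarm$arm <- "pilot"
  expect_error(study_log(badarm), "unknown arm")
  noprof <- base; noprof$profile <- c("PubMed", "  ")
  expect_error(study_log(noprof), "empty profile")
  mixed <- base; mixed$arm <- c("resource", "task")
  expect_error(study_log(mixed), "multiple arms")
})

test_that("jsonl reader reports the offending line and bad keyword keys", {
  path <- withr::local_tempfile()
  good <- paste0('{"participant_id":"p1","session_id":"s1","arm":"task",',
                 '"seq_index":1,"profile":"diagnosis","keywords":',
                 '{"disease":"asthma","drug":"","symptom":"","other":""}}')
  writeLines(c(good, "{not json"), path)
  expect_error(read_study_log(path, "jsonl"), "line 2")
  bad_cat <- sub('"other":""', '"dosage":""', good)
  writeLines(c(good, bad_cat), path)
  expect_error(read_study_log(path, "jsonl"), "unknown keyword category")
})

test_that("write then read reproduces the log in both formats", {
  spec <- behavior_spec("task", n_participants = 4L, seed = 7L)
  log <- generate_study_log(spec)
  for (fmt in c("jsonl", "csv")) {
    path <- withr::local_tempfile()
    write_study_log(log, path, fmt)
    back <- read_study_log(path, fmt)
    expect_identical(plain_events(back), plain_events(log))
  }
})

test_that("an empty log writes an empty jsonl file / header-only csv", {
  log <- searchcode:::empty_study_log()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_study_log(log, p1, "jsonl")
  expect_length(readLines(p1), 0L)
  write_study_log(log, p2, "csv")
  expect_length(readLines(p2), 1L)  # header row only
  expect_identical(plain_events(read_study_log(p2, "csv")), plain_events(log))
})

test_that("keywords survive round trips raw, without normalization", {
  log <- make_session_log(c("PubMed", "Merck"),
                          disease = c('  "otitis media" CHILD ', "heart-attack"))
  path <- withr::local_tempfile()
  write_study_log(log, path, "jsonl")
  back <- read_study_log(path, "jsonl")
  expect_identical(back$kw_disease, log$kw_disease)
})

test_that("searches minus sessions equals codable transitions per arm", {
  s <- summarize_log(paper_fixture_both())
  per <- s$per_arm
  expect_equal(per$transitions, per$searches - per$sessions)
  expect_equal(per$transitions[per$arm == "resource"], 1398L)
  expect_equal(per$transitions[per$arm == "task"], 585L)
  # degenerate case: a single one-search session has no transitions
  one <- make_session_log("PubMed")
  expect_equal(summarize_log(one)$n_transitions, 0L)
})
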