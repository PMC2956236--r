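test_that("profile coding partitions same/previous/new", {
  expect_equal(code_profile_transition("PubMed", "PubMed"), "same")
  expect_equal(code_profile_transition(c("PubMed", "Merck"), "PubMed"), "previous")
  expect_equal(code_profile_transition("PubMed", "Merck"), "new")
  expect_error(code_profile_transition(character(), "PubMed"), "history")
  # enumeration oracle over all histories from a 3-profile alphabet, length 2
  profs <- c("A", "B", "C")
  grid <- expand.grid(h1 = profs, h2 = profs, cur = profs,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    h <- c(grid$h1[i], grid$h2[i]); cur <- grid$cur[i]
    want <- if (cur == h[2]) "same" else if (cur %in% h) "previous" else "new"
    expect_equal(code_profile_transition(h, cur), want)
  }
})

test_that("action category is the 4-way collapse of profile x query", {
  expect_equal(code_action_category("same", "none"), "no_change")
  expect_equal(code_action_category("new", "none"), "change_profile_only")
  expect_equal(code_action_category("previous", "syntactic_and_semantic"),
               "change_query_and_profile")
  expect_equal(code_action_category("same", "semantic_only"),
               "change_query_only")
  # exhaustive: every combination maps to exactly one category
  for (pc in profile_codes()) {
    for (qv in query_codes()) {
      a <- code_action_category(pc, qv)
      expect_true(a %in% action_categories())
      expect_equal(a == "no_change", pc == "same" && qv == "none")
    }
  }
})

test_that("position labels: single transition is first, ends are first/last", {
  expect_equal(label_positions(1), "first")
  expect_equal(label_positions(2), c("first", "last"))
  expect_equal(label_positions(4), c("first", "middle", "middle", "last"))
  expect_equal(label_positions(0), character())
})

test_that("sessions enumerate into fully coded transitions", {
  one <- make_session_log("PubMed")
  expect_equal(nrow(enumerate_transitions(one)), 0L)
  log <- make_session_log(c("PubMed", "PubMed", "Merck", "PubMed"),
                          disease = c("asthma", "asthma child",
                                      "asthma child", "asthma child"))
  tr <- enumerate_transitions(log)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$position, c("first", "middle", "last"))
  expect_equal(tr$profile_code, c("same", "new", "previous"))
  expect_equal(tr$query_code, c("semantic_only", "none", "none"))
  expect_equal(tr$action, c("change_query_only", "change_profile_only",
                            "change_profile_only"))
  # identical resubmission is codable as no_change, not discarded
  resub <- make_session_log(c("PubMed", "PubMed"))
  expect_equal(enumerate_transitions(resub)$action, "no_change")
})

test_that("a session's first transition is never coded previous", {
  spec <- behavior_spec("resource", n_participants = 6L, seed = 3L)
  tr <- code_transitions(generate_study_log(spec))
  firsts <- tr[tr$index == 1L, ]
  expect_true(all(firsts$profile_code != "previous"))
})

test_that("combo table margins reproduce the profile and query tables", {
  tr <- code_transitions(generate_study_log(
    behavior_spec("resource", n_participants = 8L, seed = 5L)))
  combo <- build_table(tr, "combo")
  profile <- build_table(tr, "profile")
  query <- build_table(tr, "query")
  pc <- sub("\\+.*$", "", rownames(combo$counts))
  qc <- sub("^[a-z]+\\+", "", rownames(combo$counts))
  expect_equal(rowsum(combo$counts, pc)[profile$row_labels, ],
               profile$counts, ignore_attr = TRUE)
  expect_equal(rowsum(combo$counts, qc)[query$row_labels, ],
               query$counts, ignore_attr = TRUE)
  # position counts partition all transitions
  expect_equal(sum(table(tr$position)), nrow(tr))
})

test_that("pair counts equal transitions minus sessions with transitions", {
  tr <- code_transitions(generate_study_log(
    behavior_spec("task", n_participants = 8L, seed = 9L)))
  pairs <- consecutive_action_pairs(tr)
  n_active <- length(unique(tr$session_id))
  expect_equal(nrow(pairs), nrow(tr) - n_active)
  # single-transition session contributes no pair
  two <- make_session_log(c("PubMed", "Merck"))
  expect_equal(nrow(consecutive_action_pairs(code_transitions(two))), 0L)
})
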