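test_that("keyword vocabulary is pairwise variant-free", {
  expect_silent(screen_vocabulary(clinical_vocabulary()))
  expect_error(screen_vocabulary(c("apple", "apples")), "variants")
  expect_error(screen_vocabulary(c("asthma", "and")), "conjunction")
})

test_that("generation is deterministic given the seed", {
  spec <- behavior_spec("task", n_participants = 3L, seed = 77L)
  a <- generate_study_log(spec)
  b <- generate_study_log(spec)
  expect_identical(plain_events(a), plain_events(b))
  expect_identical(attr(a, "intended"), attr(b, "intended"))
  c <- generate_study_log(behavior_spec("task", n_participants = 3L, seed = 78L))
  expect_false(identical(plain_events(a), plain_events(c)))
})

test_that("a degenerate spec with all mass on same+none codes as no_change", {
  probs <- setNames(rep(0, 12), action_combinations())
  probs["same+none"] <- 1
  spec <- behavior_spec("resource", n_participants = 2L,
                        sessions_per_participant = 2L,
                        mean_session_length = 3, action_probs = probs,
                        seed = 5L)
  tr <- code_transitions(generate_study_log(spec))
  expect_true(all(tr$action == "no_change"))
})

test_that("pipeline coding equals generator intent (closed loop)", {
  spec <- behavior_spec("resource", n_participants = 6L, seed = 13L)
  log <- generate_study_log(spec)
  tr <- as.data.frame(code_transitions(log))
  it <- attr(log, "intended")
  m <- merge(tr, it, by = c("session_id", "index"))
  expect_equal(nrow(m), nrow(it))
  expect_equal(m$profile_code.x, m$profile_code.y)
  expect_equal(m$query_code, m$query_value)
  syn <- !is.na(m$subtype)
  expect_equal(m$syntactic_subtypes[syn], m$subtype[syn])
})

test_that("infeasible edit requests raise a typed condition", {
  expect_error(realize_query_edit(kw("asthma"), "syntactic_only", "word_order",
                                  cycling_chooser()),
               class = "searchcode_infeasible")
  # word order needs two distinct tokens; two categories of one token won't do
  expect_error(realize_query_edit(kw("asthma", drug = "insulin"),
                                  "syntactic_only", "word_order",
                                  cycling_chooser()),
               class = "searchcode_infeasible")
})

test_that("behavior spec validates its probability vector", {
  probs <- setNames(rep(1 / 12, 12), action_combinations())
  expect_s3_class(behavior_spec("task", action_probs = probs), "behavior_spec")
  bad <- probs; bad[1] <- 0.5
  expect_error(behavior_spec("task", action_probs = bad), "sum to 1")
  expect_error(behavior_spec("task", action_probs = probs[-1]), "named")
})

test_that("fixture builder reproduces a small custom count spec exactly", {
  combos <- setNames(c(3L, 2L, 1L, 1L, 0L, 1L, 0L, 0L, 4L, 1L, 1L, 1L),
                     action_combinations())
  spec <- fixture_spec("task", combos, n_sessions = 5L, n_searches = 20L)
  log <- fixture_from_counts(spec)
  s <- summarize_log(log)
  expect_equal(s$n_sessions, 5L)
  expect_equal(s$n_searches, 20L)
  tr <- code_transitions(log)
  combo <- build_table(tr, "combo")
  expect_equal(unname(combo$counts[, "task"]), unname(combos),
               ignore_attr = TRUE)
})

test_that("inconsistent fixture specs are rejected", {
  combos <- setNames(rep(1L, 12), action_combinations())
  expect_error(fixture_spec("task", combos, n_sessions = 5L, n_searches = 20L),
               "inconsistent")
  pos <- table6_position_counts("task")
  expect_error(fixture_spec("task", table5_counts("task"), 288L, 873L,
                            position_counts = pos + 1L),
               "inconsistent")
})

test_that("empirical action frequencies recover the spec probabilities", {
  # conditional on steps where every combination was feasible, the sampled
  # combination follows action_probs exactly; check within 3 binomial SEs
  spec <- behavior_spec("resource", n_participants = 30L, seed = 21L)
  log <- generate_study_log(spec)
  it <- attr(log, "intended")
  sub <- it[it$all_feasible, ]
  n <- nrow(sub)
  expect_gt(n, 500L)
  freq <- table(factor(paste(sub$profile_code, sub$query_value, sep = "+"),
                       levels = action_combinations())) / n
  for (combo in action_combinations()) {
    p <- spec$action_probs[[combo]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[[combo]] - p), 3 * se + 1e-12)
  }
})
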