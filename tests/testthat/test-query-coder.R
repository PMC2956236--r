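test_that("tokenizer splits on whitespace and spacing punctuation", {
  expect_equal(as.character(tokenize_query("asthma diagnosis")),
               c("asthma", "diagnosis"))
  tk <- tokenize_query("heart-attack")
  expect_equal(as.character(tk), c("heart", "attack"))
  expect_true(all(attr(tk, "grouped")))
  expect_equal(attr(tk, "group"), c(1L, 1L))
  tk2 <- tokenize_query('"otitis media" child')
  expect_equal(as.character(tk2), c("otitis", "media", "child"))
  expect_equal(attr(tk2, "grouped"), c(TRUE, TRUE, FALSE))
  expect_length(tokenize_query(""), 0L)
})

test_that("each syntactic sub-detector matches its taxonomy definition", {
  cases <- list(
    # detector, q1, q2, expected
    list(detect_capitalization_change, "IVF", "ivf", TRUE),
    list(detect_capitalization_change, "ivf", "ivf", FALSE),
    list(detect_capitalization_change, "IVF risk", "ivf danger", FALSE),
    list(detect_word_order_change, "asthma diagnosis", "diagnosis asthma", TRUE),
    list(detect_word_order_change, "asthma", "asthma", FALSE),
    list(detect_word_order_change, "a b b", "b a b", TRUE),
    list(detect_conjunction_change, "asthma AND child", "asthma child", TRUE),
    list(detect_conjunction_change, "asthma AND child", "asthma OR child", TRUE),
    list(detect_conjunction_change, "asthma child", "asthma child", FALSE),
    list(detect_spacing_change, "heart-attack", "heart attack", TRUE),
    list(detect_spacing_change, '"otitis media" child', "otitis media child", TRUE),
    list(detect_spacing_change, "heart attack", "heart attack", FALSE),
    list(detect_typographic_change, "apple", "apples", TRUE),
    list(detect_typographic_change, "behaviour", "behavior", TRUE),
    list(detect_typographic_change, "run", "walked", FALSE),
    list(detect_semantic_change, "asthma", "asthma child", TRUE),
    list(detect_semantic_change, "asthma spacer", "asthma inhaler", TRUE),
    list(detect_semantic_change, "Asthma", "asthma", FALSE))
  for (cs in cases) {
    expect_equal(cs[[1]](cs[[2]], cs[[3]]), cs[[4]],
                 info = paste(cs[[2]], "->", cs[[3]]))
  }
})

test_that("typographic variants cover stems, plurals and spellings", {
  expect_true(is_variant_pair("run", "running"))
  expect_true(is_variant_pair("apple", "apples"))
  expect_true(is_variant_pair("behaviour", "behavior"))
  expect_true(is_variant_pair("diagnosis", "diagnoses"))
  expect_false(is_variant_pair("asthma", "asthma"))  # identity is not a variant
  expect_false(is_variant_pair("run", "walked"))
  expect_false(is_variant_pair("run", "ran"))        # short words never distance-variants
})

test_that("classifier combines per-category flags into the four codes", {
  q <- classify_query_reformulation(kw("asthma"), kw("asthma"))
  expect_equal(q$value, "none"); expect_length(q$subtypes, 0L)
  q <- classify_query_reformulation(kw("IVF"), kw("ivf"))
  expect_equal(q$value, "syntactic_only")
  expect_equal(q$subtypes, "capitalization")
  q <- classify_query_reformulation(kw("asthma"), kw("Asthma child"))
  expect_equal(q$value, "syntactic_and_semantic")
  expect_equal(q$subtypes, "capitalization")
  # flags OR across categories: syntactic in one field, semantic in another
  q <- classify_query_reformulation(kw("heart-attack", drug = "insulin"),
                                    kw("heart attack", drug = "insulin steroid"))
  expect_equal(q$value, "syntactic_and_semantic")
  expect_equal(q$subtypes, "spacing")
  # adding to an empty field codes as semantic
  q <- classify_query_reformulation(kw("asthma"), kw("asthma", drug = "insulin"))
  expect_equal(q$value, "semantic_only")
  expect_error(classify_query_reformulation(c(disease = "x"), kw("x")),
               "categories")
})

test_that("classification is reflexive and none-symmetric", {
  queries <- list(kw("asthma spacer"), kw("IVF risk", drug = "nicotine"),
                  kw('"otitis media"'), kw("a AND b"), kw(""))
  for (q in queries) {
    res <- classify_query_reformulation(q, q)
    expect_equal(res$value, "none")
    expect_length(res$subtypes, 0L)
  }
  set.seed(11)
  vocab <- clinical_vocabulary()
  for (i in 1:30) {
    q1 <- kw(paste(sample(vocab, 2), collapse = " "))
    q2 <- realize_query_edit(q1, sample(query_codes()[-1], 1),
                             subtype = sample(syntactic_subtypes()[c(1, 3, 5)], 1))
    fwd <- classify_query_reformulation(q1, q2)
    bwd <- classify_query_reformulation(q2, q1)
    expect_equal(fwd$value == "none", bwd$value == "none")
  }
})

test_that("single named edits are recovered exactly and compose", {
  set.seed(23)
  vocab <- clinical_vocabulary()
  for (i in 1:40) {
    q1 <- kw(paste(sample(vocab, 3), collapse = " "),
             drug = sample(vocab, 1))
    st <- sample(syntactic_subtypes(), 1)
    q2 <- realize_query_edit(q1, "syntactic_only", st)
    res <- classify_query_reformulation(q1, q2)
    expect_equal(res$value, "syntactic_only", info = st)
    expect_equal(res$subtypes, st)
    q3 <- realize_query_edit(q1, "semantic_only")
    expect_equal(classify_query_reformulation(q1, q3)$value, "semantic_only")
    q4 <- realize_query_edit(q1, "syntactic_and_semantic", st)
    expect_equal(classify_query_reformulation(q1, q4)$value,
                 "syntactic_and_semantic", info = st)
  }
})
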