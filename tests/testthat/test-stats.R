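test_that("chi-square equals the brute-force double loop on random tables", {
  set.seed(101)
  for (i in 1:100) {
    m <- random_small_table()
    got <- pearson_chi_square(m)
    want <- chisq_oracle(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$df, want$df)
  }
})

test_that("chi-square handles degenerate and independent tables", {
  indep <- matrix(c(10, 20, 30, 60), 2, 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(pearson_chi_square(indep)$statistic, 0, tolerance = 1e-12)
  zero_row <- matrix(c(0, 0, 5, 6), 2, 2, byrow = TRUE,
                     dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(pearson_chi_square(zero_row), "degenerate")
})

test_that("wilson interval matches the score-test inversion oracle", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(5:2000, 1)
    k <- sample(0:n, 1)
    got <- wilson_interval(k, n)
    oracle <- 100 * suppressWarnings(
      stats::prop.test(k, n, correct = FALSE))$conf.int
    expect_equal(unname(got), as.numeric(oracle), tolerance = 1e-9)
  }
  expect_equal(unname(wilson_interval(0, 100))[1], 0, tolerance = 1e-9)
  expect_error(wilson_interval(1, 0), "at least 1")
})

test_that("wilson interval contains the estimate and narrows with n", {
  set.seed(303)
  for (i in 1:1000) {
    n <- sample(1:5000, 1)
    k <- sample(0:n, 1)
    ci <- unname(wilson_interval(k, n))
    pct <- 100 * k / n
    expect_true(ci[1] >= 0 && ci[2] <= 100 + 1e-9)
    expect_true(ci[1] <= pct + 1e-9 && pct <= ci[2] + 1e-9)
  }
  p <- 0.3
  widths <- vapply(c(50, 200, 800, 3200), function(n)
    diff(unname(wilson_interval(round(p * n), n))), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("z-test is antisymmetric and errors on zero standard error", {
  set.seed(404)
  for (i in 1:1000) {
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    if ((k1 %in% c(0L, n1)) && (k2 %in% c(0L, n2)) &&
        k1 / n1 == k2 / n2) next
    a <- two_proportion_z(k1, n1, k2, n2)
    b <- two_proportion_z(k2, n2, k1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(sign(a$z), sign(a$diff))
  }
  expect_equal(two_proportion_z(10, 50, 10, 50)$z, 0)
  expect_error(two_proportion_z(0, 10, 0, 20), "zero standard error")
})

test_that("build_table validates input and orders rows canonically", {
  expect_error(build_table(code_transitions(make_session_log("PubMed"))),
               "no coded transitions")
  tr <- code_transitions(make_session_log(c("PubMed", "PubMed")))
  combo <- build_table(tr, "combo")
  expect_equal(rownames(combo$counts), action_combinations())
  expect_equal(sum(combo$counts), 1L)
  expect_equal(combo$counts["same+none", "resource"], 1L)
  expect_equal(combo$grand_total, 1L)
})
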