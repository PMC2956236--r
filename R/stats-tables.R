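#' Construct a labeled two-arm contingency table
#'
#' @param counts Integer matrix (categories in rows, arms in columns) with
#'   dimnames.
#' @return An object of class `contingency_table`: a list with `row_labels`,
#'   `col_labels`, `counts`, `row_totals`, `col_totals`, `grand_total`.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry row and column labels", call. = FALSE)
  structure(list(row_labels = rownames(counts),
                 col_labels = colnames(counts),
                 counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  invisible(x)
}

#' Cross-tabulate coded transitions by a table axis
#'
#' Builds the contingency tables of the analysis from coded transitions:
#' \describe{
#'   \item{profile}{3 profile codes x arms (next profile action).}
#'   \item{query}{4 query codes x arms (next query reformulation action).}
#'   \item{combo}{12 profile-by-query combinations x arms.}
#'   \item{position_by_action}{a list of three 4 x arms tables, one per
#'     position (first/middle/last).}
#'   \item{pair}{16 consecutive action pairs x arms; sequence-final
#'     transitions (followed by stopping) are excluded, so column totals are
#'     transitions minus sessions with at least one transition.}
#' }
#' Row order follows the published table layout; column order is resource
#' then task, restricted to the arms present.
#'
#' @param transitions A `coded_transitions` data frame from
#'   [code_transitions()].
#' @param axis One of `"profile"`, `"query"`, `"combo"`,
#'   `"position_by_action"`, `"pair"`.
#' @return A [contingency_table()], or for `"position_by_action"` a named
#'   list of three of them.
#' @export
build_table <- function(transitions,
                        axis = c("profile", "query", "combo",
                                 "position_by_action", "pair")) {
  axis <- match.arg(axis)
  if (nrow(transitions) == 0) stop("no coded transitions", call. = FALSE)
  arms <- intersect(study_arms(), unique(transitions$arm))
  tab <- function(values, levels, subset = rep(TRUE, length(values)),
                  arm = transitions$arm) {
    counts <- table(factor(values[subset], levels = levels),
                    factor(arm[subset], levels = arms))
    contingency_table(unclass(as.matrix(counts)))
  }
  switch(axis,
    profile = tab(transitions$profile_code, profile_codes()),
    query = tab(transitions$query_code, query_codes()),
    combo = tab(combo_of(transitions$profile_code, transitions$query_code),
                action_combinations()),
    position_by_action = {
      out <- lapply(position_labels(), function(p)
        tab(transitions$action, action_categories(),
            subset = transitions$position == p))
      names(out) <- position_labels()
      out
    },
    pair = {
      pairs <- consecutive_action_pairs(transitions)
      if (nrow(pairs) == 0) stop("no consecutive action pairs", call. = FALSE)
      levels <- pair_labels()
      tab(paste(pairs$current, pairs$nxt, sep = " -> "), levels,
          arm = pairs$arm)
    })
}

combo_of <- function(profile_code, query_code)
  paste(profile_code, query_code, sep = "+")

#' The 12 profile-by-query action combinations
#'
#' @return Character vector `"same+none"`, ..., `"new+syntactic_and_semantic"`
#'   in published row order (profile code outer, query code inner).
#' @export
action_combinations <- function() {
  as.vector(t(outer(profile_codes(), query_codes(), paste, sep = "+")))
}

pair_labels <- function() {
  as.vector(t(outer(action_categories(), action_categories(),
                    paste, sep = " -> ")))
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic without continuity correction:
#' sum over cells of (observed - expected)^2 / expected, with expected counts
#' from the product of the margins, compared to the chi-square distribution
#' with (r - 1)(c - 1) degrees of freedom.
#'
#' @param table A [contingency_table()] or a counts matrix.
#' @return A list of class `chisq_result` with `statistic`, `df`, `p_value`.
#' @examples
#' tab <- matrix(c(557, 379, 202, 55, 639, 151), nrow = 3, byrow = TRUE,
#'               dimnames = list(c("same", "previous", "new"),
#'                               c("resource", "task")))
#' pearson_chi_square(tab)  # statistic 103.45, df 2
#' @export
pearson_chi_square <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("chi-square needs at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column total", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p %s\n", x$df, x$statistic,
              format_p(x$p_value)))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval: center (p + z^2/2n) / (1 + z^2/n),
#' half-width z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n), where z is the
#' standard normal quantile for the confidence level. Unlike the Wald
#' interval it is well-behaved at proportions near 0 or 1 and never leaves
#' \[0, 100\].
#'
#' @param count Number of successes.
#' @param n Number of trials (at least 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)` in percentage points.
#' @examples
#' wilson_interval(557, 1398)  # 37.31 to 42.43
#' @export
wilson_interval <- function(count, n, conf = 0.95) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (count < 0 || count > n) stop("count must be in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- count / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  100 * c(low = center - half, high = center + half)
}

#' Summarize a cell count as a proportion with Wilson interval
#'
#' @param count Cell count.
#' @param n Column total.
#' @param conf Confidence level.
#' @return A list of class `proportion_summary`: `count`, `n`, `pct`
#'   (percentage), `ci_low`, `ci_high` (percentage bounds), `conf_level`.
#' @export
proportion_summary <- function(count, n, conf = 0.95) {
  ci <- wilson_interval(count, n, conf)
  structure(list(count = count, n = n, pct = 100 * count / n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 conf_level = conf),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%.0f%% CI %.2f-%.2f)\n", x$count, x$n,
              x$pct, 100 * x$conf_level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Two-proportion z-test with unpooled standard error
#'
#' Tests the difference between two independent binomial proportions using
#' the unpooled standard error sqrt(p1(1-p1)/n1 + p2(1-p2)/n2); the two-sided
#' p-value comes from the standard normal distribution.
#'
#' @param count1,n1 Successes and trials in the first sample.
#' @param count2,n2 Successes and trials in the second sample.
#' @return A list of class `ztest_result` with `z`, `p_value`, and `diff`
#'   (percentage-point difference p1 - p2).
#' @examples
#' two_proportion_z(401, 1398, 54, 585)  # z = 11.43
#' @export
two_proportion_z <- function(count1, n1, count2, n2) {
  if (n1 < 1 || n2 < 1) stop("sample sizes must be at least 1", call. = FALSE)
  p1 <- count1 / n1; p2 <- count2 / n2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0)
    stop("zero standard error: both proportions degenerate", call. = FALSE)
  z <- (p1 - p2) / se
  structure(list(z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 diff = 100 * (p1 - p2)),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("diff = %.1f pp, z = %.2f, p %s\n", x$diff, x$z,
              format_p(x$p_value)))
  invisible(x)
}

# p-value display convention: "<.001" below 0.001, else 3 decimals
format_p <- function(p) {
  if (p < 0.001) "<.001" else sprintf("= %.3f", p)
}
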