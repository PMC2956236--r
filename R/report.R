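#' Code a study log and compute the full two-arm analysis
#'
#' Runs the whole pipeline: codes every consecutive-search transition,
#' builds the five table families (next profile action, next query
#' reformulation, the 12 profile-by-query combinations, actions by session
#' position, and consecutive action pairs), summarizes every cell as a
#' proportion with a Wilson score interval, and — when both arms are present
#' — computes a Pearson chi-square test per table and an unpooled
#' two-proportion z-test per row. With a single arm the tables are still
#' produced and the between-arm tests are skipped with a notice. No
#' multiple-testing correction is applied; the report records the number of
#' tests performed.
#'
#' @param log A [study_log()] with at least one codable transition.
#' @param config A [coder_config()].
#' @param conf Confidence level for the Wilson intervals (default 0.95).
#' @return An object of class `search_report`: a list with `log_summary`,
#'   `transitions` (the coded transitions), `blocks` (named list of report
#'   blocks: `profile`, `query`, `combo`, `position$first/middle/last`,
#'   `pair`; each with `table`, `cells`, `chisq`), `two_arm`, `n_tests`.
#'   Each `cells` data frame holds one row per table row with per-arm count,
#'   percentage and CI bounds plus the z-test columns.
#' @export
full_report <- function(log, config = coder_config(), conf = 0.95) {
  stopifnot(inherits(log, "study_log"))
  if (nrow(log) == 0) stop("empty study log", call. = FALSE)
  transitions <- code_transitions(log, config)
  if (nrow(transitions) == 0)
    stop("log has no codable transitions (all sessions have one search)",
         call. = FALSE)
  arms <- intersect(study_arms(), unique(transitions$arm))
  two_arm <- length(arms) == 2L

  n_tests <- 0L
  make_block <- function(tab) {
    cells <- report_cells(tab, conf, two_arm)
    chisq <- NULL
    if (two_arm && !any(tab$row_totals == 0) && !any(tab$col_totals == 0)) {
      keep <- tab$row_totals > 0
      chisq <- pearson_chi_square(tab$counts[keep, , drop = FALSE])
      n_tests <<- n_tests + 1L
    }
    if (two_arm) n_tests <<- n_tests + sum(!is.na(cells$z))
    list(table = tab, cells = cells, chisq = chisq)
  }

  blocks <- list(
    profile = make_block(build_table(transitions, "profile")),
    query = make_block(build_table(transitions, "query")),
    combo = make_block(build_table(transitions, "combo")),
    position = lapply(build_table(transitions, "position_by_action"),
                      make_block),
    pair = make_block(build_table(transitions, "pair")))

  structure(list(log_summary = summarize_log(log),
                 transitions = transitions,
                 blocks = blocks,
                 two_arm = two_arm,
                 conf = conf,
                 n_tests = n_tests),
            class = "search_report")
}

# per-row cell summaries + z test for one contingency table
report_cells <- function(tab, conf, two_arm) {
  counts <- tab$counts
  arms <- colnames(counts)
  out <- data.frame(row = rownames(counts), stringsAsFactors = FALSE)
  for (a in arms) {
    n <- tab$col_totals[[a]]
    ps <- lapply(counts[, a], function(k)
      if (n > 0) proportion_summary(k, n, conf) else NULL)
    out[[paste0("count_", a)]] <- counts[, a]
    out[[paste0("n_", a)]] <- n
    out[[paste0("pct_", a)]] <- vapply(ps, function(p)
      if (is.null(p)) NA_real_ else p$pct, numeric(1))
    out[[paste0("ci_low_", a)]] <- vapply(ps, function(p)
      if (is.null(p)) NA_real_ else p$ci_low, numeric(1))
    out[[paste0("ci_high_", a)]] <- vapply(ps, function(p)
      if (is.null(p)) NA_real_ else p$ci_high, numeric(1))
  }
  out$z <- NA_real_; out$p_value <- NA_real_; out$diff <- NA_real_
  if (two_arm) {
    n1 <- tab$col_totals[[arms[1]]]; n2 <- tab$col_totals[[arms[2]]]
    for (i in seq_len(nrow(counts))) {
      zt <- tryCatch(two_proportion_z(counts[i, 1], n1, counts[i, 2], n2),
                     error = function(e) NULL)
      if (!is.null(zt)) {
        out$z[i] <- zt$z; out$p_value[i] <- zt$p_value; out$diff[i] <- zt$diff
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.search_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

render_cell <- function(count, n, pct, lo, hi) {
  if (is.na(pct)) return(sprintf("%d", count))
  sprintf("%d (%.1f%%) (%.2f-%.2f)", count, pct, lo, hi)
}

render_block <- function(title, block, two_arm) {
  lines <- c(paste0("## ", title), "")
  cells <- block$cells
  arms <- sub("^count_", "", grep("^count_", names(cells), value = TRUE))
  header <- c("row", arms, if (two_arm) c("Z", "P"))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    vals <- vapply(arms, function(a)
      render_cell(cells[[paste0("count_", a)]][i], cells[[paste0("n_", a)]][i],
                  cells[[paste0("pct_", a)]][i], cells[[paste0("ci_low_", a)]][i],
                  cells[[paste0("ci_high_", a)]][i]), character(1))
    c(cells$row[i], vals,
      if (two_arm) c(ifelse(is.na(cells$z[i]), "-", sprintf("%.2f", cells$z[i])),
                     ifelse(is.na(cells$p_value[i]), "-",
                            sub("^= ", "", format_p(cells$p_value[i])))))
  })
  mat <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(mat), 2, max)
  fmt_row <- function(r) paste(mapply(formatC, r, width = widths,
                                      MoreArgs = list(flag = "-")),
                               collapse = "  ")
  lines <- c(lines, vapply(seq_len(nrow(mat)), function(i) fmt_row(mat[i, ]),
                           character(1)))
  if (!is.null(block$chisq)) {
    lines <- c(lines, "", sprintf("chi-square(%d) = %.2f, p %s",
                                  block$chisq$df, block$chisq$statistic,
                                  format_p(block$chisq$p_value)))
  }
  col_n <- vapply(arms, function(a) block$table$col_totals[[a]], numeric(1))
  lines <- c(lines, sprintf("column totals: %s",
                            paste(sprintf("%s n=%d", arms, col_n),
                                  collapse = ", ")), "")
  lines
}

render_report <- function(x) {
  s <- x$log_summary
  lines <- c("# Search-action coding report", "",
             sprintf("%d sessions, %d searches, %d coded transitions",
                     s$n_sessions, s$n_searches, s$n_transitions))
  for (i in seq_len(nrow(s$per_arm)))
    lines <- c(lines, sprintf("  %s: %d sessions, %d searches, %d transitions",
                              s$per_arm$arm[i], s$per_arm$sessions[i],
                              s$per_arm$searches[i], s$per_arm$transitions[i]))
  lines <- c(lines, "")
  if (!x$two_arm)
    lines <- c(lines, "NOTE: single-arm log; between-arm tests skipped.", "")
  lines <- c(lines,
             render_block("Next profile action", x$blocks$profile, x$two_arm),
             render_block("Next query reformulation action", x$blocks$query,
                          x$two_arm),
             render_block("Profile + query reformulation combinations",
                          x$blocks$combo, x$two_arm))
  for (p in names(x$blocks$position))
    lines <- c(lines, render_block(paste0("Actions at position: ", p),
                                   x$blocks$position[[p]], x$two_arm))
  lines <- c(lines, render_block("Consecutive action pairs", x$blocks$pair,
                                 x$two_arm),
             sprintf("Tests performed (uncorrected): %d", x$n_tests))
  lines
}

#' Write a report bundle to disk
#'
#' Writes the per-family tables as CSV (`table3.csv` profile, `table4.csv`
#' query, `table5.csv` combinations, `table6.csv` position-by-action,
#' `table7.csv` pairs) plus a human-readable `report.txt`. Output is
#' byte-identical for identical input logs.
#'
#' @param report A `search_report` from [full_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "search_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cells <- function(cells, path)
    utils::write.csv(cells, path, row.names = FALSE, fileEncoding = "UTF-8")
  write_cells(report$blocks$profile$cells, file.path(dir, "table3.csv"))
  write_cells(report$blocks$query$cells, file.path(dir, "table4.csv"))
  write_cells(report$blocks$combo$cells, file.path(dir, "table5.csv"))
  pos <- lapply(names(report$blocks$position), function(p) {
    cells <- report$blocks$position[[p]]$cells
    cbind(position = p, cells)
  })
  write_cells(do.call(rbind, pos), file.path(dir, "table6.csv"))
  write_cells(report$blocks$pair$cells, file.path(dir, "table7.csv"))
  writeLines(render_report(report), file.path(dir, "report.txt"))
  invisible(dir)
}
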