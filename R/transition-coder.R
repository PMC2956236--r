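#' Profile transition codes
#'
#' @return Character vector of the three profile codes: `"same"` (repeat of
#'   the immediately preceding profile), `"previous"` (used earlier in the
#'   session but not immediately preceding), `"new"` (first use in the
#'   session).
#' @export
profile_codes <- function() c("same", "previous", "new")

#' Action categories
#'
#' @return Character vector of the four combined action categories in table
#'   order.
#' @export
action_categories <- function()
  c("no_change", "change_query_only", "change_profile_only",
    "change_query_and_profile")

#' Position labels within a session
#'
#' @return Character vector `c("first", "middle", "last")`.
#' @export
position_labels <- function() c("first", "middle", "last")

#' Code the profile selection of one search against its session history
#'
#' Profiles are menu selections, so comparison is exact string equality after
#' whitespace trimming (case-sensitive). History is session-scoped: it resets
#' with each scenario question.
#'
#' @param history Character vector of the profiles of all earlier searches in
#'   the session, in order (must be non-empty: the first search of a session
#'   has no codable profile transition).
#' @param current Profile label of the current search.
#' @return `"same"`, `"previous"`, or `"new"`.
#' @examples
#' code_profile_transition("PubMed", "PubMed")              # same
#' code_profile_transition(c("PubMed", "Merck"), "PubMed")  # previous
#' code_profile_transition("PubMed", "Merck")               # new
#' @export
code_profile_transition <- function(history, current) {
  if (length(history) == 0)
    stop("profile history is empty: the session's first search has no transition",
         call. = FALSE)
  history <- trimws(history); current <- trimws(current)
  last <- history[length(history)]
  if (current == last) "same"
  else if (current %in% history) "previous"
  else "new"
}

#' Combine a profile code and a query code into an action category
#'
#' The four-way action category records whether the profile and/or the query
#' changed between consecutive searches. Any query reformulation (syntactic,
#' semantic, or both) counts as a query change; `"previous"` and `"new"`
#' both count as a profile change.
#'
#' @param profile_code One of [profile_codes()].
#' @param query_value One of [query_codes()] (a `query_code` object is also
#'   accepted).
#' @return One of [action_categories()].
#' @export
code_action_category <- function(profile_code, query_value) {
  if (inherits(query_value, "query_code")) query_value <- query_value$value
  stopifnot(profile_code %in% profile_codes(), query_value %in% query_codes())
  profile_changed <- profile_code != "same"
  query_changed <- query_value != "none"
  if (!profile_changed && !query_changed) "no_change"
  else if (!profile_changed) "change_query_only"
  else if (!query_changed) "change_profile_only"
  else "change_query_and_profile"
}

#' Position labels for an ordered run of transitions
#'
#' A session with one transition contributes a `"first"` only; with two or
#' more, the initial transition is `"first"`, the final one `"last"`, and the
#' rest `"middle"`. Hence over a log, first-count equals the number of
#' sessions with at least one transition and last-count the number with at
#' least two.
#'
#' @param k Number of transitions in the session.
#' @return Character vector of length `k` of position labels.
#' @export
label_positions <- function(k) {
  k <- as.integer(k)
  if (k <= 0L) return(character())
  if (k == 1L) return("first")
  c("first", rep("middle", k - 2L), "last")
}

code_session_transitions <- function(events, config) {
  n <- nrow(events)
  if (n < 2L) {
    return(data.frame(session_id = character(), participant_id = character(),
                      arm = character(), index = integer(),
                      profile_code = character(), query_code = character(),
                      syntactic_subtypes = character(), action = character(),
                      position = character(), stringsAsFactors = FALSE))
  }
  k <- n - 1L
  profile_code <- character(k); query_code <- character(k)
  subtypes <- character(k); action <- character(k)
  for (t in seq_len(k)) {
    i <- t + 1L
    profile_code[t] <- code_profile_transition(events$profile[seq_len(t)],
                                               events$profile[i])
    qc <- classify_query_reformulation(event_keywords(events, t),
                                       event_keywords(events, i), config)
    query_code[t] <- qc$value
    subtypes[t] <- paste(qc$subtypes, collapse = ";")
    action[t] <- code_action_category(profile_code[t], qc$value)
  }
  data.frame(session_id = events$session_id[1], participant_id = events$participant_id[1],
             arm = events$arm[1], index = seq_len(k),
             profile_code = profile_code, query_code = query_code,
             syntactic_subtypes = subtypes, action = action,
             position = label_positions(k), stringsAsFactors = FALSE)
}

#' Code every consecutive-search transition in a study log
#'
#' The unit of analysis is the transition: an ordered pair of consecutive
#' searches within a session. Each transition receives a profile code
#' ([code_profile_transition()]), a query-reformulation code
#' ([classify_query_reformulation()]), the combined action category
#' ([code_action_category()]), and a position label ([label_positions()]).
#' A session of k searches yields k - 1 transitions; single-search sessions
#' yield none.
#'
#' @param log A [study_log()] object.
#' @param config A [coder_config()].
#' @return A data frame of class `coded_transitions` with columns
#'   `session_id`, `participant_id`, `arm`, `index` (1-based within session),
#'   `profile_code`, `query_code`, `syntactic_subtypes` (semicolon-joined),
#'   `action`, `position`.
#' @export
code_transitions <- function(log, config = coder_config()) {
  stopifnot(inherits(log, "study_log"))
  out <- lapply(split_sessions(log), code_session_transitions, config = config)
  out <- if (length(out) == 0) code_session_transitions(log[0, ], config)
  else do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  structure(out, class = c("coded_transitions", "data.frame"))
}

#' Enumerate the coded transitions of a single session
#'
#' Convenience wrapper around [code_transitions()] for a log restricted to
#' one session.
#'
#' @param session A [study_log()] holding exactly one session.
#' @param config A [coder_config()].
#' @return A `coded_transitions` data frame with `nrow(session) - 1` rows.
#' @export
enumerate_transitions <- function(session, config = coder_config()) {
  stopifnot(inherits(session, "study_log"))
  if (length(unique(session$session_id)) > 1L)
    stop("`session` must contain a single session", call. = FALSE)
  code_transitions(session, config)
}

#' Consecutive pairs of action categories
#'
#' For each session with k transitions, returns the k - 1 adjacent pairs of
#' action categories (current action, next action). A session's final
#' transition has no next action (the participant stopped searching) and is
#' therefore excluded, so across a log the number of pairs equals the total
#' number of transitions minus the number of sessions with at least one
#' transition.
#'
#' @param transitions A `coded_transitions` data frame from
#'   [code_transitions()].
#' @return A data frame with columns `session_id`, `arm`, `current`, `nxt`.
#' @export
consecutive_action_pairs <- function(transitions) {
  stopifnot(is.data.frame(transitions))
  by_session <- split(as.data.frame(transitions),
                      factor(transitions$session_id,
                             levels = unique(transitions$session_id)))
  rows <- lapply(by_session, function(tr) {
    tr <- tr[order(tr$index), , drop = FALSE]
    k <- nrow(tr)
    if (k < 2L) return(NULL)
    data.frame(session_id = tr$session_id[1], arm = tr$arm[1],
               current = tr$action[seq_len(k - 1L)],
               nxt = tr$action[2:k], stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) == 0)
    data.frame(session_id = character(), arm = character(),
               current = character(), nxt = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write coded transitions to CSV
#'
#' @param transitions A `coded_transitions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transitions <- function(transitions, path) {
  utils::write.csv(as.data.frame(transitions), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.coded_transitions <- function(x, ...) {
  cat("<coded_transitions> ", nrow(x), " transitions in ",
      length(unique(x$session_id)), " sessions\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more\n", sep = "")
  invisible(x)
}
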