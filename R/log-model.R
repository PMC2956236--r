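#' @keywords internal
"_PACKAGE"

# Column layout shared by the JSONL and CSV representations.
LOG_COLUMNS <- c("participant_id", "session_id", "arm", "seq_index",
                 "profile", "kw_disease", "kw_drug", "kw_symptom", "kw_other")

#' Keyword categories available on both search systems
#'
#' Both study arms collected query keywords under four fixed categories.
#'
#' @return Character vector of the four category names.
#' @export
keyword_categories <- function() c("disease", "drug", "symptom", "other")

#' Study arms
#'
#' @return Character vector of the two arm labels: `"resource"` (profile is
#'   an information resource) and `"task"` (profile is a clinical task).
#' @export
study_arms <- function() c("resource", "task")

#' Construct a study log of search events
#'
#' A study log holds one row per submitted search. Each search belongs to a
#' search session (one participant working on one clinical scenario) and
#' records the selected profile plus the free-text keywords entered under the
#' four categories returned by [keyword_categories()].
#'
#' @param events A data frame with columns `participant_id`, `session_id`,
#'   `arm` (`"resource"` or `"task"`), `seq_index` (1-based position of the
#'   search within its session), `profile` (non-empty label) and the four
#'   keyword columns `kw_disease`, `kw_drug`, `kw_symptom`, `kw_other`
#'   (empty strings allowed).
#' @return A validated `study_log` object (a data frame). Rows are ordered by
#'   session (in order of first appearance) and `seq_index` within session.
#' @examples
#' log <- study_log(data.frame(
#'   participant_id = "p01", session_id = "s1", arm = "task",
#'   seq_index = 1:2, profile = "diagnosis",
#'   kw_disease = c("asthma", "asthma child"),
#'   kw_drug = "", kw_symptom = "", kw_other = ""))
#' summarize_log(log)
#' @export
study_log <- function(events) {
  if (!is.data.frame(events)) stop("`events` must be a data frame", call. = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LOG_COLUMNS, names(events))
  if (length(missing_cols) > 0)
    stop("missing log columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(events), LOG_COLUMNS)
  if (length(extra) > 0)
    stop("unknown log columns: ", paste(extra, collapse = ", "), call. = FALSE)
  events <- events[LOG_COLUMNS]
  for (col in setdiff(LOG_COLUMNS, "seq_index"))
    events[[col]] <- as.character(events[[col]])
  events$seq_index <- as.integer(events$seq_index)
  validate_study_log(events)
  # order sessions by first appearance, events by seq_index within session
  first_seen <- match(events$session_id, unique(events$session_id))
  events <- events[order(first_seen, events$seq_index), , drop = FALSE]
  rownames(events) <- NULL
  structure(events, class = c("study_log", "data.frame"))
}

validate_study_log <- function(events) {
  if (anyNA(events)) stop("log contains missing values", call. = FALSE)
  bad_arm <- setdiff(unique(events$arm), study_arms())
  if (length(bad_arm) > 0)
    stop("unknown arm: ", paste(bad_arm, collapse = ", "), call. = FALSE)
  if (nrow(events) == 0) return(invisible(TRUE))
  if (any(!nzchar(trimws(events$profile))))
    stop("empty profile label", call. = FALSE)
  if (any(events$seq_index < 1L))
    stop("seq_index must be a positive integer", call. = FALSE)
  by_session <- split(events, events$session_id)
  for (sid in names(by_session)) {
    s <- by_session[[sid]]
    if (length(unique(s$participant_id)) > 1L)
      stop("session ", sid, ": multiple participant_ids", call. = FALSE)
    if (length(unique(s$arm)) > 1L)
      stop("session ", sid, ": multiple arms", call. = FALSE)
    idx <- sort(s$seq_index)
    if (anyDuplicated(idx))
      stop("session ", sid, ": duplicate seq_index", call. = FALSE)
    if (!identical(idx, seq_len(nrow(s))))
      stop("session ", sid, ": seq_index not contiguous from 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a search-event log
#'
#' Reads a study log from disk. The canonical format is JSON Lines (one event
#' object per line); CSV is a flat dialect with one column per field and the
#' keyword map spread over `kw_*` columns.
#'
#' @param path Path to the log file.
#' @param format `"jsonl"` or `"csv"`.
#' @return A [study_log()] object.
#' @seealso [write_study_log()]
#' @export
read_study_log <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") read_log_jsonl(path) else read_log_csv(path)
}

read_log_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_study_log())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("parse error at line ", i, ": ", conditionMessage(e),
                           call. = FALSE))
    needed <- c("participant_id", "session_id", "arm", "seq_index",
                "profile", "keywords")
    if (!all(needed %in% names(rec)))
      stop("parse error at line ", i, ": missing field(s) ",
           paste(setdiff(needed, names(rec)), collapse = ", "), call. = FALSE)
    kw <- rec$keywords
    unknown <- setdiff(names(kw), keyword_categories())
    if (length(unknown) > 0)
      stop("parse error at line ", i, ": unknown keyword category ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (!all(keyword_categories() %in% names(kw)))
      stop("parse error at line ", i, ": keyword categories incomplete",
           call. = FALSE)
    rows[[i]] <- data.frame(
      participant_id = as.character(rec$participant_id),
      session_id = as.character(rec$session_id),
      arm = as.character(rec$arm),
      seq_index = as.integer(rec$seq_index),
      profile = as.character(rec$profile),
      kw_disease = as.character(kw$disease),
      kw_drug = as.character(kw$drug),
      kw_symptom = as.character(kw$symptom),
      kw_other = as.character(kw$other),
      stringsAsFactors = FALSE)
  }
  study_log(do.call(rbind, rows))
}

read_log_csv <- function(path) {
  events <- utils::read.csv(path, colClasses = "character",
                            check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(events) == 0) return(empty_study_log())
  study_log(events)
}

empty_study_log <- function() {
  events <- data.frame(participant_id = character(), session_id = character(),
                       arm = character(), seq_index = integer(),
                       profile = character(), kw_disease = character(),
                       kw_drug = character(), kw_symptom = character(),
                       kw_other = character(), stringsAsFactors = FALSE)
  structure(events, class = c("study_log", "data.frame"))
}

#' Write a search-event log
#'
#' Inverse of [read_study_log()]: writing then reading reproduces the log
#' field-for-field in both formats.
#'
#' @param log A [study_log()] object.
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_study_log <- function(log, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(log, "study_log"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(log), path, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(log) > 0) {
    for (i in seq_len(nrow(log))) {
      rec <- list(
        participant_id = log$participant_id[i],
        session_id = log$session_id[i],
        arm = log$arm[i],
        seq_index = log$seq_index[i],
        profile = log$profile[i],
        keywords = list(disease = log$kw_disease[i], drug = log$kw_drug[i],
                        symptom = log$kw_symptom[i], other = log$kw_other[i]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con,
                 useBytes = TRUE)
    }
  }
  invisible(path)
}

#' Summarize a study log
#'
#' Counts sessions, searches, and codable transitions (consecutive-search
#' pairs) overall and per arm. The number of codable transitions in an arm is
#' its searches minus its sessions, since each session of k searches yields
#' k - 1 transitions.
#'
#' @param log A [study_log()] object.
#' @return A list with `n_sessions`, `n_searches`, `n_transitions`, and a
#'   per-arm data frame `per_arm`.
#' @export
summarize_log <- function(log) {
  stopifnot(inherits(log, "study_log"))
  sess_arm <- unique(log[c("session_id", "arm")])
  per_arm <- lapply(study_arms(), function(a) {
    n_sess <- sum(sess_arm$arm == a)
    n_srch <- sum(log$arm == a)
    data.frame(arm = a, sessions = n_sess, searches = n_srch,
               transitions = n_srch - n_sess, stringsAsFactors = FALSE)
  })
  per_arm <- do.call(rbind, per_arm)
  per_arm <- per_arm[per_arm$sessions > 0, , drop = FALSE]
  rownames(per_arm) <- NULL
  list(n_sessions = nrow(sess_arm),
       n_searches = nrow(log),
       n_transitions = nrow(log) - nrow(sess_arm),
       per_arm = per_arm)
}

#' @export
summary.study_log <- function(object, ...) {
  s <- summarize_log(object)
  structure(s, class = "study_log_summary")
}

#' @export
print.study_log_summary <- function(x, ...) {
  cat("Study log:", x$n_sessions, "sessions,", x$n_searches, "searches,",
      x$n_transitions, "codable transitions\n")
  if (nrow(x$per_arm) > 0) print(x$per_arm, row.names = FALSE)
  invisible(x)
}

#' @export
print.study_log <- function(x, ...) {
  s <- summarize_log(x)
  cat("<study_log> ", s$n_searches, " searches in ", s$n_sessions,
      " sessions (", paste(s$per_arm$arm, collapse = " + "), ")\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more events\n", sep = "")
  invisible(x)
}

# split a log into per-session event data frames, preserving order
split_sessions <- function(log) {
  split(as.data.frame(log), factor(log$session_id, levels = unique(log$session_id)))
}

# keyword map (named character of the 4 categories) for event row i
event_keywords <- function(events, i) {
  kw <- c(disease = events$kw_disease[i], drug = events$kw_drug[i],
          symptom = events$kw_symptom[i], other = events$kw_other[i])
  kw
}
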