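#' Clinical keyword vocabulary for synthetic logs
#'
#' About fifty clinical-flavored tokens screened so that no two are
#' typographic variants of each other under [is_variant_pair()]; realized
#' semantic edits are therefore always classified as semantic, never as
#' typographic variation.
#'
#' @return Character vector of lowercase tokens.
#' @export
clinical_vocabulary <- function() {
  c("asthma", "spacer", "inhaler", "child", "nicotine", "patch",
    "myocardial", "infarction", "cervical", "cancer", "fertilization",
    "risk", "sudden", "infant", "death", "sibling", "anaerobic",
    "organism", "osteomyelitis", "diabetes", "glucosamine",
    "osteoarthritis", "epinephrine", "antivenom", "anaphylaxis",
    "tympanostomy", "otitis", "grommet", "effusion", "hearing",
    "language", "evidence", "therapy", "guideline", "dosage",
    "pediatric", "allergy", "bronchitis", "pneumonia", "sepsis",
    "fracture", "migraine", "insulin", "steroid", "vaccine", "biopsy",
    "lesion", "tumor", "renal", "breast")
}

#' Screen a keyword vocabulary for variant collisions
#'
#' @param words Character vector of candidate tokens.
#' @param config A [coder_config()].
#' @return `words`, invisibly; errors naming the first colliding pair.
#' @export
screen_vocabulary <- function(words, config = coder_config()) {
  words <- tolower(words)
  if (anyDuplicated(words)) stop("duplicate vocabulary tokens", call. = FALSE)
  if (any(words %in% config$conjunctions))
    stop("vocabulary contains a conjunction token", call. = FALSE)
  n <- length(words)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is_variant_pair(words[i], words[j], config))
        stop("vocabulary tokens are typographic variants: ",
             words[i], " / ", words[j], call. = FALSE)
    }
  }
  invisible(words)
}

# --- choosers: pluggable index pickers so the same realization code runs
#     randomly (generator) or deterministically (fixture builder) -----------

#' Index choosers for edit realization
#'
#' [realize_query_edit()] makes its arbitrary choices (which field, which
#' word, which vocabulary token) through a chooser: a function taking the
#' number of options and returning one index. `random_chooser()` draws from
#' the current RNG stream; `cycling_chooser()` cycles deterministically
#' (round-robin) and is used by the fixture builder, which must be free of
#' randomness.
#'
#' @return A function `f(n) -> integer in 1..n`.
#' @export
random_chooser <- function() function(n) if (n <= 1L) 1L else sample.int(n, 1L)

#' @rdname random_chooser
#' @export
cycling_chooser <- function() {
  i <- 0L
  function(n) {
    i <<- i + 1L
    ((i - 1L) %% n) + 1L
  }
}

# try options in rotated order starting from the chooser's pick
pick_order <- function(n, chooser) {
  if (n == 0L) return(integer())
  start <- chooser(n)
  ((seq_len(n) + start - 2L) %% n) + 1L
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("searchcode_infeasible", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# --- keyword map helpers --------------------------------------------------

split_units <- function(field) {
  u <- strsplit(field, "[[:space:]]+")[[1]]
  u[nzchar(u)]
}

join_units <- function(units) paste(units, collapse = " ")

is_plain_word <- function(u) grepl("^[A-Za-z]+$", u)

content_units <- function(units, config) units[!is_conjunction(units, config)]

total_content_units <- function(kw, config) {
  sum(vapply(kw, function(f) length(content_units(split_units(f), config)),
             integer(1)))
}

# which single-subtype / semantic edits are realizable on this keyword map
edit_feasibility <- function(kw, config) {
  fields <- lapply(kw, split_units)
  content <- lapply(fields, content_units, config = config)
  plain <- lapply(content, function(u) u[is_plain_word(u)])
  has_adjacent_distinct <- function(u) {
    if (length(u) < 2L) return(FALSE)
    for (i in seq_len(length(u) - 1L)) {
      if (tolower(u[i]) != tolower(u[i + 1L]) &&
          !is_variant_pair(tolower(u[i]), tolower(u[i + 1L]), config))
        return(TRUE)
    }
    FALSE
  }
  c(capitalization = any(lengths(plain) > 0L),
    typographic = any(lengths(plain) > 0L),
    word_order = any(vapply(content, has_adjacent_distinct, logical(1))),
    conjunction = any(vapply(fields, function(u) any(is_conjunction(u, config)),
                             logical(1))) ||
      any(lengths(content) >= 2L),
    spacing = any(vapply(fields, function(u) any(grepl("-", u, fixed = TRUE)),
                         logical(1))) ||
      any(vapply(plain, length, integer(1)) >= 2L),
    semantic = TRUE)
}

# --- single-edit realizers: each returns a modified copy of kw or NULL ----

edit_capitalization <- function(kw, chooser, config) {
  cand <- list()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    idx <- which(is_plain_word(units) & !is_conjunction(units, config))
    for (i in idx) cand[[length(cand) + 1L]] <- c(cat, i)
  }
  for (k in pick_order(length(cand), chooser)) {
    cat <- cand[[k]][1]; i <- as.integer(cand[[k]][2])
    units <- split_units(kw[[cat]])
    w <- units[i]
    units[i] <- if (grepl("[A-Z]", w)) tolower(w)
    else paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    out <- kw; out[[cat]] <- join_units(units)
    return(out)
  }
  NULL
}

edit_typographic <- function(kw, chooser, config) {
  cand <- list()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    idx <- which(is_plain_word(units) & !is_conjunction(units, config))
    for (i in idx) cand[[length(cand) + 1L]] <- c(cat, i)
  }
  for (k in pick_order(length(cand), chooser)) {
    cat <- cand[[k]][1]; i <- as.integer(cand[[k]][2])
    units <- split_units(kw[[cat]])
    w <- units[i]
    units[i] <- if (grepl("s$", w, ignore.case = TRUE))
      substr(w, 1, nchar(w) - 1L) else paste0(w, "s")
    out <- kw; out[[cat]] <- join_units(units)
    return(out)
  }
  NULL
}

edit_word_order <- function(kw, chooser, config) {
  cand <- list()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    cu_idx <- which(!is_conjunction(units, config))
    if (length(cu_idx) < 2L) next
    for (k in seq_len(length(cu_idx) - 1L)) {
      i <- cu_idx[k]; j <- cu_idx[k + 1L]
      if (tolower(units[i]) != tolower(units[j]) &&
          !is_variant_pair(tolower(units[i]), tolower(units[j]), config))
        cand[[length(cand) + 1L]] <- c(cat, i, j)
    }
  }
  for (k in pick_order(length(cand), chooser)) {
    cat <- cand[[k]][1]
    i <- as.integer(cand[[k]][2]); j <- as.integer(cand[[k]][3])
    units <- split_units(kw[[cat]])
    units[c(i, j)] <- units[c(j, i)]
    out <- kw; out[[cat]] <- join_units(units)
    return(out)
  }
  NULL
}

edit_conjunction <- function(kw, chooser, config) {
  # prefer removing an existing conjunction, else insert AND between words
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    ci <- which(is_conjunction(units, config))
    if (length(ci) > 0L) {
      out <- kw; out[[cat]] <- join_units(units[-ci[1]])
      return(out)
    }
  }
  cand <- character()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    if (length(content_units(units, config)) >= 2L) cand <- c(cand, cat)
  }
  for (k in pick_order(length(cand), chooser)) {
    cat <- cand[k]
    units <- split_units(kw[[cat]])
    units <- append(units, "AND", after = 1L)
    out <- kw; out[[cat]] <- join_units(units)
    return(out)
  }
  NULL
}

edit_spacing <- function(kw, chooser, config) {
  # prefer splitting an existing hyphen group, else hyphenate two words
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    hi <- which(grepl("-", units, fixed = TRUE))
    if (length(hi) > 0L) {
      units[hi[1]] <- sub("-", " ", units[hi[1]], fixed = TRUE)
      out <- kw; out[[cat]] <- join_units(units)
      return(out)
    }
  }
  cand <- list()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    for (i in seq_len(max(0L, length(units) - 1L))) {
      if (is_plain_word(units[i]) && is_plain_word(units[i + 1L]) &&
          !is_conjunction(units[i], config) &&
          !is_conjunction(units[i + 1L], config))
        cand[[length(cand) + 1L]] <- c(cat, i)
    }
  }
  for (k in pick_order(length(cand), chooser)) {
    cat <- cand[[k]][1]; i <- as.integer(cand[[k]][2])
    units <- split_units(kw[[cat]])
    units[i] <- paste0(units[i], "-", units[i + 1L])
    units <- units[-(i + 1L)]
    out <- kw; out[[cat]] <- join_units(units)
    return(out)
  }
  NULL
}

# one semantic edit: add, remove, or replace a content keyword; growth is
# bounded (no adds past 10 content tokens) and the map never empties
edit_semantic <- function(kw, chooser, config, vocabulary) {
  total <- total_content_units(kw, config)
  ops <- c(if (total < 10L) "add",
           if (total >= 3L) "remove",
           if (total >= 1L) "replace")
  for (op in ops[pick_order(length(ops), chooser)]) {
    out <- switch(op,
      add = semantic_add(kw, chooser, config, vocabulary),
      remove = semantic_remove(kw, chooser, config),
      replace = semantic_replace(kw, chooser, config, vocabulary))
    if (!is.null(out)) return(out)
  }
  NULL
}

semantic_add <- function(kw, chooser, config, vocabulary) {
  cat <- names(kw)[chooser(length(kw))]
  present <- tolower(unlist(lapply(kw, split_units), use.names = FALSE))
  avail <- vocabulary[!vapply(vocabulary, function(w)
    any(vapply(present, variant_or_equal, logical(1), w2 = w, config = config)),
    logical(1))]
  if (length(avail) == 0L) return(NULL)
  w <- avail[chooser(length(avail))]
  units <- c(split_units(kw[[cat]]), w)
  out <- kw; out[[cat]] <- join_units(units)
  out
}

semantic_remove <- function(kw, chooser, config) {
  cand <- list()
  for (cat in names(kw)) {
    units <- split_units(kw[[cat]])
    idx <- which(!is_conjunction(units, config))
    for (i in idx) cand[[length(cand) + 1L]] <- c(cat, i)
  }
  if (length(cand) == 0L) return(NULL)
  k <- chooser(length(cand))
  cat <- cand[[k]][1]; i <- as.integer(cand[[k]][2])
  units <- split_units(kw[[cat]])
  # keep conjunction tokens untouched: deleting one would also code as a
  # conjunction change, not a pure semantic removal
  units <- units[-i]
  out <- kw; out[[cat]] <- join_units(units)
  out
}

semantic_replace <- function(kw, chooser, config, vocabulary) {
  removed <- semantic_remove(kw, chooser, config)
  if (is.null(removed)) return(NULL)
  # add in the same category that was edited, if possible
  semantic_add(removed, chooser, config, vocabulary)
}

#' Realize a query edit of a requested reformulation code
#'
#' Produces a new keywords map such that
#' [classify_query_reformulation()]`(current, new)` yields exactly the
#' requested code (and, for syntactic changes, exactly the requested
#' subtype). Syntactic-and-semantic targets are realized by applying the
#' syntactic edit and the semantic edit to two different keyword categories.
#' Every candidate edit is verified against the classifier before being
#' returned; an unrealizable request (e.g. a word-order change on a
#' single-token query) raises a condition of class `searchcode_infeasible`.
#'
#' @param current Named character vector over [keyword_categories()].
#' @param value Target code, one of [query_codes()].
#' @param subtype Target syntactic subtype (one of [syntactic_subtypes()]),
#'   required when `value` includes a syntactic change.
#' @param chooser A chooser function ([random_chooser()] or
#'   [cycling_chooser()]) resolving arbitrary choices.
#' @param config A [coder_config()].
#' @param vocabulary Tokens available for semantic additions (pairwise
#'   non-variant, see [screen_vocabulary()]).
#' @return The new keywords map (named character vector).
#' @export
realize_query_edit <- function(current, value, subtype = NULL,
                               chooser = random_chooser(),
                               config = coder_config(),
                               vocabulary = clinical_vocabulary()) {
  stopifnot(value %in% query_codes())
  kw <- current[keyword_categories()]
  if (anyNA(kw)) stop("keyword map must name all categories", call. = FALSE)
  if (value == "none") return(kw)
  syntactic <- value %in% c("syntactic_only", "syntactic_and_semantic")
  if (syntactic && is.null(subtype))
    stop("`subtype` required for a syntactic target", call. = FALSE)
  if (syntactic) stopifnot(subtype %in% syntactic_subtypes())

  verify <- function(new_kw, want_value, want_subtypes) {
    qc <- classify_query_reformulation(kw, new_kw, config)
    identical(qc$value, want_value) &&
      identical(qc$subtypes, sort(want_subtypes))
  }

  if (value == "semantic_only") {
    for (attempt in seq_len(8L)) {
      out <- edit_semantic(kw, chooser, config, vocabulary)
      if (!is.null(out) && verify(out, "semantic_only", character())) return(out)
    }
    stop_infeasible("cannot realize a semantic edit on this keyword map")
  }

  apply_syntactic <- function(base_kw) {
    fn <- switch(subtype,
                 capitalization = edit_capitalization,
                 typographic = edit_typographic,
                 word_order = edit_word_order,
                 conjunction = edit_conjunction,
                 spacing = edit_spacing)
    fn(base_kw, chooser, config)
  }

  if (value == "syntactic_only") {
    for (attempt in seq_len(8L)) {
      out <- apply_syntactic(kw)
      if (!is.null(out) && verify(out, "syntactic_only", subtype)) return(out)
    }
    stop_infeasible(paste0("cannot realize a ", subtype,
                           " edit on this keyword map"))
  }

  # syntactic_and_semantic: syntactic edit in one category, semantic in another
  for (attempt in seq_len(8L)) {
    step1 <- apply_syntactic(kw)
    if (is.null(step1)) break
    changed <- names(kw)[which(kw != step1)]
    others <- setdiff(names(kw), changed)
    sem_kw <- step1[others]
    for (att2 in seq_len(4L)) {
      sem_out <- edit_semantic(sem_kw, chooser, config, vocabulary)
      if (is.null(sem_out)) next
      out <- step1
      out[others] <- sem_out[others]
      if (verify(out, "syntactic_and_semantic", subtype)) return(out)
    }
  }
  stop_infeasible(paste0("cannot realize ", subtype,
                         " + semantic on this keyword map"))
}
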