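#' Configuration for the query-reformulation coder
#'
#' Collects the tunable pieces of the reformulation taxonomy: the conjunction
#' vocabulary, the punctuation characters treated as word spacing/grouping,
#' and the typographic-variant relation (suffix-stripping stemmer plus a
#' bounded edit-distance rule).
#'
#' @param conjunctions Tokens treated as boolean conjunctions, matched
#'   case-insensitively as standalone words. Default `c("and", "or", "not")`.
#' @param spacing_chars Punctuation characters that split, group or merge
#'   words rather than carry content. Default hyphen, double quote, comma,
#'   semicolon and slash.
#' @param variant_max_dist Maximum Levenshtein distance for two words to
#'   count as spelling variants. Default 2.
#' @param variant_prefix_len Length of the shared prefix required by the
#'   edit-distance variant rule. Default 3.
#' @param variant_min_len Minimum word length for the edit-distance variant
#'   rule (short words are never distance-variants). Default 4.
#' @param use_stemmer If `TRUE` (default) words with equal suffix-stripped
#'   stems are typographic variants (covers plurals and -ing/-ed forms).
#' @return An object of class `coder_config`.
#' @export
coder_config <- function(conjunctions = c("and", "or", "not"),
                         spacing_chars = c("-", "\"", ",", ";", "/"),
                         variant_max_dist = 2L,
                         variant_prefix_len = 3L,
                         variant_min_len = 4L,
                         use_stemmer = TRUE) {
  structure(list(conjunctions = tolower(conjunctions),
                 spacing_chars = spacing_chars,
                 variant_max_dist = as.integer(variant_max_dist),
                 variant_prefix_len = as.integer(variant_prefix_len),
                 variant_min_len = as.integer(variant_min_len),
                 use_stemmer = isTRUE(use_stemmer)),
            class = "coder_config")
}

#' Tokenize a query string
#'
#' Splits a free-text query into word tokens. Separators are whitespace plus
#' the configured spacing punctuation. Words joined by spacing punctuation
#' (e.g. `"heart-attack"`) or enclosed in double quotes (e.g.
#' `"\"otitis media\""`) are split into their component words but share a
#' group id and carry a grouping mark, so that grouping edits are visible to
#' the spacing detector.
#'
#' @param text Query string (may be empty).
#' @param config A [coder_config()].
#' @return Character vector of tokens with attributes `group` (integer group
#'   id per token) and `grouped` (logical: token was part of a punctuation or
#'   quote group).
#' @examples
#' tokenize_query("heart-attack")     # "heart" "attack", grouped
#' tokenize_query("asthma diagnosis") # two independent tokens
#' @export
tokenize_query <- function(text, config = coder_config()) {
  stopifnot(length(text) == 1L)
  if (is.na(text)) text <- ""
  words <- character(); groups <- integer(); grouped <- logical()
  gid <- 0L
  emit <- function(ws, in_group) {
    ws <- ws[nzchar(ws)]
    if (length(ws) == 0) return()
    if (in_group || length(ws) > 1L) {
      gid <<- gid + 1L
      words <<- c(words, ws)
      groups <<- c(groups, rep(gid, length(ws)))
      grouped <<- c(grouped, rep(TRUE, length(ws)))
    } else {
      gid <<- gid + 1L
      words <<- c(words, ws)
      groups <<- c(groups, gid)
      grouped <<- c(grouped, FALSE)
    }
  }
  punct <- setdiff(config$spacing_chars, "\"")
  punct_class <- posix_class(punct, with_space = FALSE)
  punct_re <- paste0(posix_class(punct, with_space = TRUE), "+")
  # alternate segments outside / inside double quotes
  segs <- strsplit(text, "\"", fixed = TRUE)[[1]]
  if (length(segs) == 0) segs <- ""
  for (k in seq_along(segs)) {
    inside <- (k %% 2L == 0L)   # even segments are inside quotes
    seg_words <- strsplit(segs[[k]], punct_re)[[1]]
    if (inside) {
      emit(seg_words, in_group = TRUE)
    } else {
      # outside quotes: whitespace separates units; punctuation groups within a unit
      units <- strsplit(segs[[k]], "[[:space:]]+")[[1]]
      for (u in units) {
        if (!nzchar(u)) next
        parts <- strsplit(u, punct_re)[[1]]
        parts <- parts[nzchar(parts)]
        if (length(parts) == 0) next
        # a unit containing spacing punctuation is a group even if one word
        has_punct <- grepl(punct_class, u)
        emit(parts, in_group = has_punct && length(parts) > 1L)
      }
    }
  }
  structure(words, group = groups, grouped = grouped)
}

# Build a POSIX bracket expression from literal characters: "]" must come
# first and "-" last to stay literal; "^" must not be first.
posix_class <- function(chars, with_space = TRUE) {
  rest <- setdiff(chars, c("]", "-"))
  paste0("[",
         if ("]" %in% chars) "]",
         paste(rest, collapse = ""),
         if (with_space) "[:space:]",
         if ("-" %in% chars) "-",
         "]")
}

is_conjunction <- function(words, config) tolower(words) %in% config$conjunctions

# tokenized field split into content / conjunction parts with structure info
field_tokens <- function(text, config) {
  tk <- tokenize_query(text, config)
  grp <- attr(tk, "group"); marked <- attr(tk, "grouped")
  conj <- is_conjunction(tk, config)
  raw <- as.character(tk)[!conj]
  list(raw = raw,                              # content words, original case
       folded = tolower(raw),                  # case-folded content words
       groups = match(grp[!conj], unique(grp[!conj])),  # normalized group ids
       marked = marked[!conj],
       conj = tolower(as.character(tk)[conj])) # conjunction subsequence
}

#' Suffix-stripping stemmer
#'
#' A light stemmer used by the typographic-variant relation: strips the
#' suffixes `ies` (to `y`), `es`, `s`, `ing`, `ed`, un-doubling a doubled
#' final consonant after `ing`/`ed`, and never reduces a word below three
#' characters.
#'
#' @param word A single lowercase word.
#' @return The stemmed word.
#' @export
stem_word <- function(word) {
  w <- word
  n <- nchar(w)
  strip <- function(w, suf, repl = "") {
    if (nchar(w) - nchar(suf) + nchar(repl) < 3L) return(NULL)
    if (endsWith(w, suf)) paste0(substr(w, 1L, nchar(w) - nchar(suf)), repl) else NULL
  }
  undouble <- function(w) {
    n <- nchar(w)
    if (n >= 4L && substr(w, n, n) == substr(w, n - 1L, n - 1L) &&
        !substr(w, n, n) %in% c("l", "s", "z")) substr(w, 1L, n - 1L) else w
  }
  for (rule in list(c("ies", "y"), c("es", ""), c("s", ""))) {
    out <- strip(w, rule[1], rule[2])
    if (!is.null(out)) return(out)
  }
  for (suf in c("ing", "ed")) {
    out <- strip(w, suf)
    if (!is.null(out)) return(undouble(out))
  }
  w
}

#' Typographic-variant relation between two words
#'
#' Two distinct words are typographic variants when they share a
#' suffix-stripped stem (plurals, inflections) or when they are within a
#' small Levenshtein distance of each other with a shared prefix (spelling
#' variants such as behaviour/behavior). Matching is case-insensitive.
#'
#' @param w1,w2 Single words.
#' @param config A [coder_config()].
#' @return `TRUE` if the words are variants (but not identical).
#' @examples
#' is_variant_pair("apple", "apples")       # TRUE (shared stem)
#' is_variant_pair("behaviour", "behavior") # TRUE (edit distance 1)
#' is_variant_pair("run", "walked")         # FALSE
#' @export
is_variant_pair <- function(w1, w2, config = coder_config()) {
  w1 <- tolower(w1); w2 <- tolower(w2)
  if (w1 == w2) return(FALSE)
  if (config$use_stemmer && stem_word(w1) == stem_word(w2)) return(TRUE)
  p <- config$variant_prefix_len
  if (nchar(w1) >= config$variant_min_len && nchar(w2) >= config$variant_min_len &&
      substr(w1, 1L, p) == substr(w2, 1L, p) &&
      utils::adist(w1, w2)[1, 1] <= config$variant_max_dist) return(TRUE)
  FALSE
}

variant_or_equal <- function(w1, w2, config) {
  tolower(w1) == tolower(w2) || is_variant_pair(w1, w2, config)
}

# Greedy in-order token matching between two folded word sequences:
# exact matches first (each i takes the first unused equal j), then a variant
# pass for the leftovers. Returns j_of (NA where unmatched) and unmatched
# indices on both sides.
match_tokens <- function(f1, f2, config) {
  used2 <- rep(FALSE, length(f2))
  j_of <- rep(NA_integer_, length(f1))
  for (i in seq_along(f1)) {
    for (j in seq_along(f2)) {
      if (!used2[j] && f2[j] == f1[i]) { j_of[i] <- j; used2[j] <- TRUE; break }
    }
  }
  for (i in seq_along(f1)) {
    if (!is.na(j_of[i])) next
    for (j in seq_along(f2)) {
      if (!used2[j] && is_variant_pair(f1[i], f2[j], config)) {
        j_of[i] <- j; used2[j] <- TRUE; break
      }
    }
  }
  list(j_of = j_of,
       unmatched1 = which(is.na(j_of)),
       unmatched2 = which(!used2))
}

letters_stream <- function(ft) paste(ft$folded, collapse = "")

structure_signature <- function(ft) list(ft$folded, ft$groups, ft$marked)

# Core per-field comparison: returns the set of syntactic subtypes that fire
# plus the semantic flag, well-defined on combined edits. Layer order:
# grouping/spacing -> tokenization -> conjunctions -> case -> stem/variant.
compare_field <- function(q1, q2, config) {
  if (identical(q1, q2)) return(list(subtypes = character(), semantic = FALSE))
  t1 <- field_tokens(q1, config)
  t2 <- field_tokens(q2, config)
  subtypes <- character()
  if (!identical(t1$conj, t2$conj)) subtypes <- c(subtypes, "conjunction")
  same_letters <- identical(letters_stream(t1), letters_stream(t2))
  if (same_letters &&
      !identical(structure_signature(t1), structure_signature(t2)))
    subtypes <- c(subtypes, "spacing")
  m <- match_tokens(t1$folded, t2$folded, config)
  complete <- length(m$unmatched1) == 0 && length(m$unmatched2) == 0
  # same letter stream means a pure regrouping: no keyword added or removed
  semantic <- !complete && !same_letters
  for (i in seq_along(m$j_of)) {
    j <- m$j_of[i]
    if (is.na(j)) next
    if (t1$folded[i] == t2$folded[j]) {
      if (t1$raw[i] != t2$raw[j]) subtypes <- c(subtypes, "capitalization")
    } else {
      subtypes <- c(subtypes, "typographic")
    }
  }
  if (complete && length(m$j_of) > 0 &&
      any(m$j_of != seq_along(m$j_of)))
    subtypes <- c(subtypes, "word_order")
  list(subtypes = unique(subtypes), semantic = semantic)
}

#' Syntactic change sub-detectors
#'
#' Each detector tests one row of the syntactic reformulation taxonomy on a
#' pair of query strings, after removal of conjunction tokens:
#' \describe{
#'   \item{capitalization}{token sequences equal case-insensitively,
#'     position-wise, but differing case-sensitively ("IVF" to "ivf").}
#'   \item{word order}{case-folded token multisets equal but ordered
#'     differently ("asthma diagnosis" to "diagnosis asthma").}
#'   \item{conjunction}{the subsequence of conjunction tokens (AND/OR/NOT)
#'     differs while the content tokens still match completely.}
#'   \item{spacing}{the concatenated case-folded letter streams agree but the
#'     word boundaries or grouping differ ("heart-attack" to "heart attack",
#'     quoting a phrase).}
#'   \item{typographic}{every aligned token pair is equal or a typographic
#'     variant and at least one pair is a variant ("apple" to "apples",
#'     "behaviour" to "behavior").}
#' }
#'
#' @param q1,q2 Query strings.
#' @param config A [coder_config()].
#' @return Logical scalar.
#' @name syntactic_detectors
NULL

#' @rdname syntactic_detectors
#' @export
detect_capitalization_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  length(t1$raw) == length(t2$raw) &&
    identical(t1$folded, t2$folded) &&
    !identical(t1$raw, t2$raw)
}

#' @rdname syntactic_detectors
#' @export
detect_word_order_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  identical(sort(t1$folded), sort(t2$folded)) &&
    !identical(t1$folded, t2$folded)
}

#' @rdname syntactic_detectors
#' @export
detect_conjunction_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  if (identical(t1$conj, t2$conj)) return(FALSE)
  m <- match_tokens(t1$folded, t2$folded, config)
  length(m$unmatched1) == 0 && length(m$unmatched2) == 0
}

#' @rdname syntactic_detectors
#' @export
detect_spacing_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  identical(letters_stream(t1), letters_stream(t2)) &&
    !identical(structure_signature(t1), structure_signature(t2))
}

#' @rdname syntactic_detectors
#' @export
detect_typographic_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  if (length(t1$folded) != length(t2$folded) || length(t1$folded) == 0)
    return(FALSE)
  pairs_ok <- mapply(variant_or_equal, t1$folded, t2$folded,
                     MoreArgs = list(config = config))
  any_variant <- any(t1$folded != t2$folded)
  all(pairs_ok) && any_variant
}

#' Detect a semantic reformulation between two query strings
#'
#' A semantic reformulation adds, removes, or replaces content keywords:
#' after case-folding, conjunction removal and collapsing typographic
#' variants, the token multisets of the two queries differ. Pure regrouping
#' edits (identical letter streams, e.g. merging "heart attack" to
#' "heartattack") are spacing changes, not semantic ones.
#'
#' @param q1,q2 Query strings.
#' @param config A [coder_config()].
#' @return Logical scalar.
#' @export
detect_semantic_change <- function(q1, q2, config = coder_config()) {
  t1 <- field_tokens(q1, config); t2 <- field_tokens(q2, config)
  if (identical(letters_stream(t1), letters_stream(t2))) return(FALSE)
  m <- match_tokens(t1$folded, t2$folded, config)
  length(m$unmatched1) > 0 || length(m$unmatched2) > 0
}

#' Query reformulation codes
#'
#' @return Character vector of the four query-change codes in table order.
#' @export
query_codes <- function()
  c("none", "syntactic_only", "semantic_only", "syntactic_and_semantic")

#' Syntactic subtypes
#'
#' @return Character vector of the five syntactic sub-detector names.
#' @export
syntactic_subtypes <- function()
  c("capitalization", "word_order", "conjunction", "spacing", "typographic")

#' Classify the reformulation between two consecutive searches
#'
#' Compares the previous and current keyword maps category by category
#' (disease, drug, symptom, other) and combines the per-category flags: the
#' result is `"none"` when no detector fires in any category,
#' `"syntactic_only"` when only syntactic sub-detectors fire,
#' `"semantic_only"` when only the semantic detector fires, and
#' `"syntactic_and_semantic"` otherwise. On combined edits within one field,
#' tokens are aligned greedily (exact matches first, then typographic
#' variants) so that e.g. a case flip co-occurring with an added keyword is
#' still recognized as a capitalization change.
#'
#' @param prev,curr Named character vectors with the four
#'   [keyword_categories()] as names (empty strings allowed).
#' @param config A [coder_config()].
#' @return A list of class `query_code` with elements `value` (one of
#'   [query_codes()]) and `subtypes` (character vector of fired syntactic
#'   sub-detectors, empty unless the value includes a syntactic change).
#' @examples
#' kw <- function(disease = "", drug = "", symptom = "", other = "")
#'   c(disease = disease, drug = drug, symptom = symptom, other = other)
#' classify_query_reformulation(kw("IVF"), kw("ivf"))
#' classify_query_reformulation(kw("asthma"), kw("asthma child"))
#' @export
classify_query_reformulation <- function(prev, curr, config = coder_config()) {
  for (nm in c("prev", "curr")) {
    kw <- get(nm)
    if (!all(keyword_categories() %in% names(kw)))
      stop("`", nm, "` must name all keyword categories: ",
           paste(keyword_categories(), collapse = ", "), call. = FALSE)
  }
  subtypes <- character(); semantic <- FALSE
  for (cat in keyword_categories()) {
    res <- compare_field(unname(prev[[cat]]), unname(curr[[cat]]), config)
    subtypes <- union(subtypes, res$subtypes)
    semantic <- semantic || res$semantic
  }
  syntactic <- length(subtypes) > 0
  value <- if (!syntactic && !semantic) "none"
  else if (syntactic && !semantic) "syntactic_only"
  else if (!syntactic) "semantic_only"
  else "syntactic_and_semantic"
  structure(list(value = value,
                 subtypes = sort(subtypes)),
            class = "query_code")
}

#' @export
print.query_code <- function(x, ...) {
  cat("<query_code>", x$value)
  if (length(x$subtypes) > 0) cat(" {", paste(x$subtypes, collapse = ", "), "}")
  cat("\n")
  invisible(x)
}
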