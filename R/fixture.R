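#' Published 12-cell action counts per arm
#'
#' The per-arm counts of the 12 profile-by-query action combinations
#' (profile code same/previous/new crossed with query code none/syntactic/
#' semantic/both), as reported for the two study arms.
#'
#' @param arm `"resource"` or `"task"`.
#' @return Named integer vector over [action_combinations()].
#' @export
table5_counts <- function(arm = c("resource", "task")) {
  arm <- match.arg(arm)
  counts <- if (arm == "resource")
    c(67L, 193L, 203L, 94L, 120L, 18L, 36L, 28L, 401L, 83L, 87L, 68L)
  else
    c(74L, 99L, 123L, 83L, 16L, 10L, 17L, 12L, 54L, 28L, 39L, 30L)
  names(counts) <- action_combinations()
  counts
}

#' Published position-by-action counts per arm
#'
#' Counts of the four action categories at the first, middle, and last
#' transition of a session, per arm.
#'
#' @param arm `"resource"` or `"task"`.
#' @return 3 x 4 integer matrix (positions x [action_categories()]).
#' @export
table6_position_counts <- function(arm = c("resource", "task")) {
  arm <- match.arg(arm)
  m <- if (arm == "resource")
    matrix(c(9L, 115L, 82L, 57L,
             47L, 303L, 359L, 204L,
             11L, 72L, 80L, 59L), nrow = 3, byrow = TRUE)
  else
    matrix(c(31L, 100L, 24L, 34L,
             32L, 144L, 34L, 57L,
             11L, 61L, 12L, 45L), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(position_labels(), action_categories())
  m
}

#' Specify an exact-count fixture
#'
#' A fixture spec pins down the coded contingency tables a constructed log
#' must reproduce exactly: the 12-cell action-combination counts, the session
#' and search totals, and (optionally) the position-by-action marginals.
#'
#' @param arm `"resource"` or `"task"`.
#' @param combo_counts Named integer vector over [action_combinations()].
#' @param n_sessions Number of sessions.
#' @param n_searches Number of searches; `sum(combo_counts)` must equal
#'   `n_searches - n_sessions` (one transition per consecutive search pair).
#' @param position_counts Optional 3 x 4 matrix (positions x action
#'   categories); must collapse to `combo_counts` by action, and its
#'   first/last row sums must be achievable session counts.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(arm, combo_counts, n_sessions, n_searches,
                         position_counts = NULL) {
  arm <- match.arg(arm, study_arms())
  if (!identical(sort(names(combo_counts)), sort(action_combinations())))
    stop("combo_counts must be named by the 12 action combinations",
         call. = FALSE)
  combo_counts <- as.integer(combo_counts[action_combinations()])
  names(combo_counts) <- action_combinations()
  total <- sum(combo_counts)
  if (total != n_searches - n_sessions)
    stop("inconsistent fixture: sum(combo_counts) = ", total,
         " but n_searches - n_sessions = ", n_searches - n_sessions,
         call. = FALSE)
  if (!is.null(position_counts)) {
    position_counts <- as.matrix(position_counts)
    if (!identical(dim(position_counts), c(3L, 4L)))
      stop("position_counts must be 3 x 4 (positions x actions)", call. = FALSE)
    dimnames(position_counts) <- list(position_labels(), action_categories())
    by_action <- colSums(position_counts)
    collapse <- collapse_to_actions(combo_counts)
    if (!all(by_action == collapse))
      stop("inconsistent fixture: position_counts do not collapse to combo_counts",
           call. = FALSE)
    n_first <- sum(position_counts["first", ])
    n_last <- sum(position_counts["last", ])
    n_middle <- sum(position_counts["middle", ])
    if (n_first > n_sessions || n_last > n_first ||
        n_middle != total - n_first - n_last)
      stop("inconsistent fixture: position marginals are not realizable",
           call. = FALSE)
  }
  structure(list(arm = arm, combo_counts = combo_counts,
                 n_sessions = as.integer(n_sessions),
                 n_searches = as.integer(n_searches),
                 position_counts = position_counts),
            class = "fixture_spec")
}

# collapse 12 combo counts to the 4 action categories
collapse_to_actions <- function(combo_counts) {
  pc <- sub("\\+.*$", "", names(combo_counts))
  qv <- sub("^[a-z]+\\+", "", names(combo_counts))
  action <- mapply(code_action_category, pc, qv)
  out <- tapply(combo_counts, factor(action, levels = action_categories()), sum)
  out[is.na(out)] <- 0L
  as.integer(out)
}

#' Published-table fixture specs
#'
#' Ready-made [fixture_spec()]s whose coded tables reproduce the published
#' per-arm contingency tables exactly: 12-cell action counts, session and
#' search totals (310 sessions / 1708 searches resource; 288 / 873 task),
#' and the position-by-action marginals.
#'
#' @param arm `"resource"` or `"task"`.
#' @return A [fixture_spec()].
#' @export
fixture_preset <- function(arm = c("resource", "task")) {
  arm <- match.arg(arm)
  totals <- if (arm == "resource") c(310L, 1708L) else c(288L, 873L)
  fixture_spec(arm, table5_counts(arm), totals[1], totals[2],
               table6_position_counts(arm))
}

#' Deterministically construct a log matching an exact-count fixture
#'
#' Builds a study log whose coded transitions reproduce the fixture's
#' 12-cell action-combination table (and, when given, its position-by-action
#' marginals) cell-for-cell. Construction is entirely deterministic:
#' session lengths are spread as evenly as possible, action combinations are
#' dealt round-robin, and the syntactic subtype realizing each syntactic
#' change cycles through the five subtypes. Structural constraints are
#' honored during dealing: a session's first transition is never coded
#' `"previous"`, and any `"previous"` transition is preceded in its session
#' by a `"new"` one.
#'
#' @param spec A [fixture_spec()].
#' @param config A [coder_config()].
#' @return A [study_log()] with attribute `"intended"` as in
#'   [generate_study_log()] (all rows have `all_feasible = NA`).
#' @export
fixture_from_counts <- function(spec, config = coder_config()) {
  stopifnot(inherits(spec, "fixture_spec"))
  combos <- spec$combo_counts
  total <- sum(combos)
  if (total == 0L && spec$n_sessions == 0L) stop("empty fixture", call. = FALSE)

  # --- session skeleton: how many transitions per session ---------------
  if (!is.null(spec$position_counts)) {
    n_first <- sum(spec$position_counts["first", ])
    n_last <- sum(spec$position_counts["last", ])
  } else {
    n_first <- min(spec$n_sessions, total)
    n_single <- max(0L, 2L * n_first - total)
    n_last <- n_first - n_single
  }
  n_zero <- spec$n_sessions - n_first
  n_single <- n_first - n_last
  t_multi <- total - n_single
  if (n_last > 0L) {
    base <- t_multi %/% n_last
    rem <- t_multi %% n_last
    multi_k <- c(rep(base + 1L, rem), rep(base, n_last - rem))
    if (any(multi_k < 2L))
      stop("inconsistent fixture: cannot give every last-position session two transitions",
           call. = FALSE)
  } else multi_k <- integer()

  # --- allocate combos to positions -------------------------------------
  pc_of <- sub("\\+.*$", "", names(combos))
  action_of <- mapply(code_action_category, pc_of,
                      sub("^[a-z]+\\+", "", names(combos)))
  remaining <- combos
  alloc <- matrix(0L, nrow = 3, ncol = length(combos),
                  dimnames = list(position_labels(), names(combos)))
  pos_need <- if (!is.null(spec$position_counts)) spec$position_counts else {
    # no marginals given: derive capacities and fill actions greedily
    caps <- c(first = n_first, middle = total - n_first - n_last, last = n_last)
    m <- matrix(0L, 3, 4, dimnames = list(position_labels(), action_categories()))
    # previous-profile combos cannot sit at a session's first transition
    prev_by_action <- tapply(combos[pc_of == "previous"],
                             factor(action_of[pc_of == "previous"],
                                    levels = action_categories()), sum)
    prev_by_action[is.na(prev_by_action)] <- 0L
    tot_by_action <- collapse_to_actions(combos)
    names(tot_by_action) <- action_categories()
    left <- caps
    for (a in action_categories()) {
      nonprev <- tot_by_action[a] - prev_by_action[a]
      take_first <- min(nonprev, left["first"])
      m["first", a] <- take_first; left["first"] <- left["first"] - take_first
      rest <- tot_by_action[a] - take_first
      take_mid <- min(rest, left["middle"])
      m["middle", a] <- take_mid; left["middle"] <- left["middle"] - take_mid
      m["last", a] <- rest - take_mid; left["last"] <- left["last"] - (rest - take_mid)
    }
    if (any(left != 0L)) stop("inconsistent fixture: cannot place all transitions",
                              call. = FALSE)
    m
  }
  for (a in action_categories()) {
    members <- which(action_of == a)
    # first-position slots must come from non-previous combos
    ord_first <- members[order(pc_of[members] == "previous")]
    need <- pos_need["first", a]
    for (k in ord_first) {
      if (pc_of[k] == "previous") next
      take <- min(need, remaining[k])
      alloc["first", k] <- take; remaining[k] <- remaining[k] - take
      need <- need - take
    }
    if (need > 0L)
      stop("inconsistent fixture: first-position ", a,
           " slots exceed non-previous counts", call. = FALSE)
    # middle prefers previous-profile combos, last takes the rest
    for (p in c("middle", "last")) {
      need <- pos_need[p, a]
      ord <- if (p == "middle") members[order(pc_of[members] != "previous")]
      else members
      for (k in ord) {
        take <- min(need, remaining[k])
        alloc[p, k] <- alloc[p, k] + take; remaining[k] <- remaining[k] - take
        need <- need - take
      }
      if (need > 0L) stop("inconsistent fixture: cannot fill ", p,
                          "-position ", a, " slots", call. = FALSE)
    }
  }

  pool <- function(p) rep(names(combos), alloc[p, ])

  # --- deal combos to session slots --------------------------------------
  n_multi <- length(multi_k)
  first_pool <- pool("first")
  first_pool <- first_pool[order(sub("\\+.*$", "", first_pool) != "new")]
  first_slot <- character(n_first)
  # multi sessions first so they preferentially hold the new-profile firsts
  first_slot[seq_len(n_first)] <- first_pool
  multi_first <- first_slot[seq_len(n_multi)]
  single_first <- if (n_single > 0L) first_slot[n_multi + seq_len(n_single)] else character()

  mid_cap <- multi_k - 2L
  middles <- lapply(seq_len(n_multi), function(i) character(0))
  deal_round_robin <- function(items, eligible) {
    # deal items one at a time over eligible sessions with middle capacity
    i <- 1L
    for (item in items) {
      placed <- FALSE
      for (step in seq_len(max(1L, n_multi))) {
        s <- ((i - 1L) %% n_multi) + 1L
        i <- i + 1L
        if (eligible[s] && length(middles[[s]]) < mid_cap[s]) {
          middles[[s]][[length(middles[[s]]) + 1L]] <<- item
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("inconsistent fixture: no eligible middle slot for ", item,
             call. = FALSE)
    }
  }
  mid_pool <- pool("middle")
  mid_pc <- sub("\\+.*$", "", mid_pool)
  deal_round_robin(mid_pool[mid_pc == "new"], rep(TRUE, n_multi))
  has_new_early <- function(s) {
    sub("\\+.*$", "", multi_first[s]) == "new" ||
      any(sub("\\+.*$", "", middles[[s]]) == "new")
  }
  elig <- vapply(seq_len(n_multi), has_new_early, logical(1))
  deal_round_robin(mid_pool[mid_pc == "previous"], elig)
  deal_round_robin(mid_pool[mid_pc == "same"], rep(TRUE, n_multi))

  last_pool <- pool("last")
  last_pc <- sub("\\+.*$", "", last_pool)
  elig <- vapply(seq_len(n_multi), has_new_early, logical(1))
  last_slot <- character(n_multi)
  for (item in last_pool[last_pc == "previous"]) {
    s <- which(elig & !nzchar(last_slot))[1]
    if (is.na(s))
      stop("inconsistent fixture: no eligible session for a previous-profile last transition",
           call. = FALSE)
    last_slot[s] <- item
  }
  rest <- last_pool[last_pc != "previous"]
  open <- which(!nzchar(last_slot))
  last_slot[open] <- rest

  # --- realize sessions ---------------------------------------------------
  # within-session order: first, then middles sorted new < same < previous,
  # then last, so every previous-profile transition follows a new one
  order_middles <- function(items) {
    pc <- sub("\\+.*$", "", items)
    items[order(match(pc, c("new", "same", "previous")))]
  }
  session_combos <- c(
    lapply(seq_len(n_multi), function(s)
      c(multi_first[s], order_middles(middles[[s]]), last_slot[s])),
    as.list(single_first),
    rep(list(character()), n_zero))

  subtype_cycle <- cycling_chooser()
  chooser <- cycling_chooser()
  vocab <- clinical_vocabulary()
  profile_counter <- 0L
  mint <- function() {
    profile_counter <<- profile_counter + 1L
    sprintf("P%03d", profile_counter)
  }
  events <- vector("list", length(session_combos))
  intents <- vector("list", length(session_combos))
  for (s in seq_along(session_combos)) {
    sid <- sprintf("%s-f%04d", spec$arm, s)
    pid <- sprintf("%s-fp%02d", spec$arm, ((s - 1L) %/% 8L) + 1L)
    seq_combos <- session_combos[[s]]
    ev_profile <- mint()
    kw <- c(disease = paste(vocab[1:2], collapse = " "),
            drug = "", symptom = "", other = "")
    ev_kw <- list(kw)
    it <- list()
    for (t in seq_along(seq_combos)) {
      pc <- sub("\\+.*$", "", seq_combos[t])
      qv <- sub("^[a-z]+\\+", "", seq_combos[t])
      last <- ev_profile[length(ev_profile)]
      subtype <- NA_character_
      if (qv %in% c("syntactic_only", "syntactic_and_semantic")) {
        feas <- edit_feasibility(kw, config)
        new_kw <- NULL
        for (try in seq_len(5L)) {
          cand <- syntactic_subtypes()[subtype_cycle(5L)]
          if (!feas[[cand]]) next
          new_kw <- tryCatch(
            realize_query_edit(kw, qv, cand, chooser, config, vocab),
            searchcode_infeasible = function(e) NULL)
          if (!is.null(new_kw)) { subtype <- cand; break }
        }
        if (is.null(new_kw))
          stop("fixture realization failed: no feasible syntactic subtype",
               call. = FALSE)
      } else {
        new_kw <- realize_query_edit(kw, qv, chooser = chooser,
                                     config = config, vocabulary = vocab)
      }
      new_profile <- switch(pc,
        same = last,
        new = mint(),
        previous = {
          prior <- setdiff(unique(ev_profile), last)
          if (length(prior) == 0L)
            stop("fixture realization failed: previous-profile transition without history",
                 call. = FALSE)
          prior[1]
        })
      ev_profile <- c(ev_profile, new_profile)
      ev_kw[[length(ev_kw) + 1L]] <- new_kw
      kw <- new_kw
      it[[t]] <- data.frame(session_id = sid, index = t, profile_code = pc,
                            query_value = qv, subtype = subtype,
                            all_feasible = NA, stringsAsFactors = FALSE)
    }
    kwm <- do.call(rbind, ev_kw)
    events[[s]] <- data.frame(
      participant_id = pid, session_id = sid, arm = spec$arm,
      seq_index = seq_along(ev_profile), profile = ev_profile,
      kw_disease = kwm[, "disease"], kw_drug = kwm[, "drug"],
      kw_symptom = kwm[, "symptom"], kw_other = kwm[, "other"],
      stringsAsFactors = FALSE)
    intents[[s]] <- if (length(it) > 0) do.call(rbind, it) else NULL
  }
  log <- study_log(do.call(rbind, events))
  intended <- do.call(rbind, intents)
  rownames(intended) <- NULL
  attr(log, "intended") <- intended
  log
}
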