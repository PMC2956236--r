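#' Default profile vocabularies for the two arms
#'
#' Six profiles per arm: information resources for the resource-based system,
#' clinical tasks for the task-based system. These are defaults, not hard
#' constraints; coding depends only on profile identity and history.
#'
#' @param arm `"resource"` or `"task"`.
#' @return Character vector of 6 profile labels.
#' @export
profile_vocabulary <- function(arm = c("resource", "task")) {
  arm <- match.arg(arm)
  if (arm == "resource")
    c("PubMed", "MIMS", "Therapeutic Guidelines", "Merck Manual",
      "Harrisons", "HealthInsite")
  else
    c("diagnosis", "drug information", "etiology", "patient education",
      "treatment", "other")
}

#' Behavioral parameters for the synthetic log generator
#'
#' A behavior spec fixes the study conditions a generated arm emulates: how
#' many participants and sessions, how long sessions run, and the probability
#' of each of the 12 profile-by-query action combinations governing every
#' consecutive-search transition. The presets mirror the two observed search
#' strategies: breadth-first (switch profiles while holding the query,
#' resource-arm signature) and depth-first (hold the profile while
#' reformulating the query, task-arm signature).
#'
#' @param arm `"resource"` or `"task"`.
#' @param n_participants Number of participants (default: 39 resource, 36
#'   task, the study's allocation).
#' @param sessions_per_participant Sessions (scenario questions) per
#'   participant; default 8.
#' @param mean_session_length Mean searches per session; the session length
#'   is drawn from a shifted geometric law on {1, 2, ...} with this mean.
#'   Defaults to the observed per-arm means (1708/310 resource, 873/288
#'   task).
#' @param action_probs Named probability vector over
#'   [action_combinations()]; must sum to 1. Defaults to the observed
#'   per-arm action mix ([behavior_preset()]).
#' @param profiles Profile vocabulary (default [profile_vocabulary()] for
#'   the arm).
#' @param vocabulary Keyword vocabulary for semantic edits; screened with
#'   [screen_vocabulary()].
#' @param seed Integer seed making generation fully deterministic.
#' @return An object of class `behavior_spec`.
#' @export
behavior_spec <- function(arm = c("resource", "task"),
                          n_participants = NULL,
                          sessions_per_participant = 8L,
                          mean_session_length = NULL,
                          action_probs = NULL,
                          profiles = NULL,
                          vocabulary = clinical_vocabulary(),
                          seed = 1L) {
  arm <- match.arg(arm)
  if (is.null(n_participants))
    n_participants <- if (arm == "resource") 39L else 36L
  if (is.null(mean_session_length))
    mean_session_length <- if (arm == "resource") 1708 / 310 else 873 / 288
  if (is.null(action_probs))
    action_probs <- behavior_preset(if (arm == "resource") "breadth" else "depth")
  if (is.null(profiles)) profiles <- profile_vocabulary(arm)
  if (!identical(sort(names(action_probs)), sort(action_combinations())))
    stop("action_probs must be named by the 12 action combinations",
         call. = FALSE)
  action_probs <- action_probs[action_combinations()]
  if (abs(sum(action_probs) - 1) > 1e-8)
    stop("action_probs must sum to 1", call. = FALSE)
  if (any(action_probs < 0)) stop("negative action probability", call. = FALSE)
  if (mean_session_length < 1)
    stop("mean_session_length must be at least 1", call. = FALSE)
  screen_vocabulary(vocabulary)
  structure(list(arm = arm,
                 n_participants = as.integer(n_participants),
                 sessions_per_participant = as.integer(sessions_per_participant),
                 mean_session_length = mean_session_length,
                 action_probs = action_probs,
                 profiles = profiles,
                 vocabulary = vocabulary,
                 seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Preset action-probability vectors
#'
#' `"breadth"` and `"depth"` are the observed per-arm action mixes of the
#' resource-based and task-based systems respectively (the breadth-first and
#' depth-first search strategies), obtained by normalizing the published
#' 12-cell action counts ([table5_counts()]).
#'
#' @param preset `"breadth"` or `"depth"`.
#' @return Named probability vector over [action_combinations()].
#' @export
behavior_preset <- function(preset = c("breadth", "depth")) {
  preset <- match.arg(preset)
  counts <- table5_counts(if (preset == "breadth") "resource" else "task")
  counts / sum(counts)
}

# draw from a shifted geometric on {1, 2, ...} with the given mean
draw_session_length <- function(mean_len) {
  if (mean_len <= 1) return(1L)
  1L + stats::rgeom(1L, prob = 1 / mean_len)
}

sample_index <- function(probs) {
  sample.int(length(probs), 1L, prob = probs)
}

#' Generate a synthetic study log
#'
#' Builds a full search-event log from a [behavior_spec()]. Each session
#' draws its length, starts from a random profile and random keywords, and
#' then realizes one sampled action combination per transition: the profile
#' move follows the sampled profile code and the query edit is produced by
#' [realize_query_edit()], so the pipeline's coding of each generated
#' transition equals the generator's intention (closed loop).
#'
#' Feasibility renormalization: when the session history cannot support a
#' combination (no previously used distinct profile for `"previous"`, all six
#' profiles already used for `"new"`, or a syntactic edit with no realizable
#' subtype), its probability mass is redistributed proportionally over the
#' feasible combinations.
#'
#' @param spec A [behavior_spec()].
#' @return A [study_log()]. The attribute `"intended"` holds a data frame
#'   with the generator's intended codes per transition (`session_id`,
#'   `index`, `profile_code`, `query_value`, `subtype`) plus `all_feasible`,
#'   `TRUE` for transitions where no renormalization occurred (on those the
#'   sampled combination follows `action_probs` exactly).
#' @export
generate_study_log <- function(spec) {
  stopifnot(inherits(spec, "behavior_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n_sessions <- spec$n_participants * spec$sessions_per_participant
  session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)
  combos <- action_combinations()
  combo_profile <- sub("\\+.*$", "", combos)
  combo_query <- sub("^[a-z]+\\+", "", combos)
  chooser <- random_chooser()

  events <- vector("list", n_sessions)
  intents <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    set.seed(session_seeds[s])
    sid <- sprintf("%s-s%04d", spec$arm, s)
    pid <- sprintf("%s-p%02d", spec$arm,
                   ((s - 1L) %/% spec$sessions_per_participant) + 1L)
    len <- draw_session_length(spec$mean_session_length)
    profiles_used <- sample(spec$profiles, 1L)
    start_words <- sample(spec$vocabulary, 2L)
    kw <- c(disease = paste(start_words, collapse = " "),
            drug = "", symptom = "", other = "")
    ev_profile <- profiles_used
    ev_kw <- list(kw)
    it <- list()
    for (t in seq_len(len - 1L)) {
      last <- ev_profile[length(ev_profile)]
      distinct_prior <- setdiff(unique(ev_profile), last)
      unused <- setdiff(spec$profiles, unique(ev_profile))
      subtype_ok <- edit_feasibility(kw, coder_config())
      feasible <- rep(TRUE, length(combos))
      feasible[combo_profile == "previous"] <- length(distinct_prior) > 0L
      feasible[combo_profile == "new"] <- feasible[combo_profile == "new"] &
        length(unused) > 0L
      needs_syntactic <- combo_query %in% c("syntactic_only",
                                            "syntactic_and_semantic")
      feasible[needs_syntactic] <- feasible[needs_syntactic] &
        any(subtype_ok[syntactic_subtypes()])
      all_feasible <- all(feasible)
      repeat {
        if (!any(feasible)) stop("no feasible action combination", call. = FALSE)
        probs <- spec$action_probs * feasible
        k <- sample_index(probs / sum(probs))
        pc <- combo_profile[k]; qv <- combo_query[k]
        subtype <- NA_character_
        new_kw <- tryCatch({
          if (qv %in% c("syntactic_only", "syntactic_and_semantic")) {
            options <- syntactic_subtypes()[subtype_ok[syntactic_subtypes()]]
            subtype <- options[chooser(length(options))]
            realize_query_edit(kw, qv, subtype, chooser,
                               vocabulary = spec$vocabulary)
          } else {
            realize_query_edit(kw, qv, chooser = chooser,
                               vocabulary = spec$vocabulary)
          }
        }, searchcode_infeasible = function(e) NULL)
        if (!is.null(new_kw)) break
        feasible[k] <- FALSE
        all_feasible <- FALSE
      }
      new_profile <- switch(pc,
        same = last,
        previous = distinct_prior[chooser(length(distinct_prior))],
        new = unused[chooser(length(unused))])
      ev_profile <- c(ev_profile, new_profile)
      ev_kw[[length(ev_kw) + 1L]] <- new_kw
      kw <- new_kw
      it[[t]] <- data.frame(session_id = sid, index = t, profile_code = pc,
                            query_value = qv, subtype = subtype,
                            all_feasible = all_feasible,
                            stringsAsFactors = FALSE)
    }
    kwm <- do.call(rbind, ev_kw)
    events[[s]] <- data.frame(
      participant_id = pid, session_id = sid, arm = spec$arm,
      seq_index = seq_len(len), profile = ev_profile,
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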