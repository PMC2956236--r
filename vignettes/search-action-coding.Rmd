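---
title: "Coding search actions and query reformulations in session logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding search actions and query reformulations in session logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchcode)
```

## The coding model

A search-event log records one row per submitted search: participant,
session, study arm (resource-based or task-based system), 1-based position
within the session, the selected profile, and free-text keywords in four
fixed categories (disease, drug, symptom, other). A *session* is the
sequence of searches one participant submits for one clinical scenario
question; the analysis unit is the *transition*, an ordered pair of
consecutive searches. A session of $k$ searches yields $k-1$ transitions,
so per arm the number of transitions is searches minus sessions.

Each transition is coded on two independent axes and their combination:

* **Profile code.** Comparing the current profile to the session history:
  `same` if it equals the immediately preceding profile, `previous` if it
  differs from the preceding one but was used earlier in the session, `new`
  otherwise. The three codes partition all cases; `previous` is only
  possible from the second transition on, since the first transition sees a
  one-element history. Profile history is session-scoped — it resets with
  each scenario question. Profiles are menu selections, so comparison is
  exact string equality after whitespace trimming, case-sensitive.

* **Query code.** The keyword change is `none`, `syntactic_only`,
  `semantic_only`, or `syntactic_and_semantic`. Each of the four keyword
  category fields is compared with its same-category counterpart and flags
  are OR'd across categories; a keyword moved between categories therefore
  codes as a removal plus an addition, i.e. semantic.

* **Action category and position.** The 4-way collapse (no change /
  change query only / change profile only / change query and profile), and
  a first/middle/last label: a single-transition session is labeled
  `first`; with two or more, the endpoints are `first` and `last` and the
  rest `middle`. Consequently, over a log, `first` counts sessions with at
  least one transition and `last` counts sessions with at least two — which
  is also why consecutive-pair counts equal transitions minus sessions with
  a transition (the sequence-final action has no next action).

An identical resubmission (same profile, identical keywords) is a codable
`no_change` transition, not a discard.

## The reformulation taxonomy

Syntactic reformulations alter surface form only. The five sub-detectors
are defined against a fixed normalization cascade — grouping/spacing
punctuation, tokenization, conjunction removal, case folding,
stem/variant collapse — with each detector firing when equality status
changes at exactly its layer:

| Subtype        | Fires when | Example |
|----------------|------------|---------|
| capitalization | aligned tokens equal case-insensitively, differ case-sensitively | `IVF` → `ivf` |
| word order     | token multisets equal, order differs | `asthma diagnosis` → `diagnosis asthma` |
| conjunction    | the AND/OR/NOT subsequence differs | `asthma AND child` → `asthma child` |
| spacing        | case-folded letter streams equal, word boundaries or grouping differ | `heart-attack` → `heart attack` |
| typographic    | aligned tokens are stem-equal or close spelling variants | `apple` → `apples`, `behaviour` → `behavior` |

Semantic reformulation is a change in the multiset of normalized content
tokens: adding, removing, or replacing keywords, including filling a
previously empty category.

Two definitional choices deserve emphasis:

* **Combined edits are resolved by alignment, not position.** When a case
  flip co-occurs with an added keyword (`asthma` → `Asthma child`), a
  purely position-wise comparison is undefined. The classifier greedily
  matches tokens in order — exact matches first, then typographic
  variants — and reads the per-pair layer differences off the matching;
  unmatched tokens on either side are the semantic signal. The standalone
  `detect_*()` functions keep the stricter single-edit definitions.

* **A pure regrouping is never semantic.** If the concatenated case-folded
  letter streams of two fields are equal (`heartattack` → `heart attack`),
  no keyword was added or removed, so the semantic detector is suppressed
  for that field and the change codes as spacing. Without this guard every
  merge/split would spuriously count as a keyword replacement.

* **Variant status has precedence over replacement.** An aligned pair that
  is a typographic variant is syntactic; only pairs beyond variant status
  (and unmatched tokens) count toward semantic change. Otherwise every
  plural would also be a "replace".

## Tunable parameters

All knobs live in `coder_config()`:

* `conjunctions` (default `and`, `or`, `not`, matched case-insensitively
  as standalone tokens): the three attested boolean connectors.
* `spacing_chars` (default hyphen, double quote, comma, semicolon, slash):
  punctuation treated as word spacing/grouping rather than content.
  Hyphen and quotes are the motivating cases; the rest are conservative
  extensions.
* The typographic-variant relation: two distinct words are variants iff
  (a) they share a suffix-stripped stem, or (b) Levenshtein distance
  ≤ `variant_max_dist` (2) with a shared `variant_prefix_len` (3) prefix
  and both at least `variant_min_len` (4) characters. (a) covers plurals
  and inflections, (b) spelling variants such as behaviour/behavior, while
  the length/prefix guards keep short-word false positives rare. The
  stemmer (`stem_word()`) strips `ies/es/s/ing/ed` with final-consonant
  undoubling and a three-character minimum stem; it is deliberately small,
  transparent, and switchable (`use_stemmer = FALSE`). The original
  study never published its exact variant rule, so this relation is a
  declared, configurable operationalization — the tests pin its behavior,
  not its uniqueness.

Statistical conventions: Wilson score intervals at 95% with
`z = qnorm(0.975)` ≈ 1.959964 (using 1.96 shifts the second CI decimal);
chi-square without continuity correction, asymptotic p-values; z-tests
with the *unpooled* standard error (the pooled form gives visibly
different statistics on the same counts, e.g. ≈ −6.2 instead of −5.28 on
67/1398 vs 74/585); two-sided p-values, displayed as `<.001` below 0.001.
No multiple-testing correction is applied — matching the original
analysis — and the report records the number of tests performed.

## The synthetic-data generator

`behavior_spec()` fixes the conditions a generated arm emulates. Defaults
are the study's own conditions: 39/36 participants (resource/task), 8
sessions each, mean session lengths 1708/310 ≈ 5.51 and 873/288 ≈ 3.03
searches drawn from a shifted geometric law on {1, 2, ...} (the simplest
one-parameter law on session lengths with the right mean and a monotone
tail), and per-transition action probabilities given by the published
per-arm action mixes (`behavior_preset("breadth")` /
`behavior_preset("depth")`).

Each transition samples one of the 12 profile-by-query combinations and
realizes it: the profile move follows the sampled code, and
`realize_query_edit()` constructs a keyword edit that the classifier
provably codes as intended — every candidate edit is verified against
`classify_query_reformulation()` before being accepted. Combined
syntactic+semantic targets are realized in two *different* categories,
which keeps the two signals well-posed. When history makes a combination
infeasible (no distinct prior profile for `previous`, all six profiles
used for `new`, no realizable syntactic subtype), its mass is
redistributed proportionally over the feasible combinations; the
generator records, per transition, whether any renormalization occurred,
and statistical-recovery tests condition on the unrenormalized subset,
where the sampled distribution is exactly `action_probs`.

The keyword vocabulary (~50 clinical tokens) is screened pairwise against
the variant relation at build time, so a semantic addition can never be
mistaken for a typographic variant. Randomness is ordinary base-R RNG
with per-session substreams derived from the spec seed, so generation is
reproducible and insensitive to session count changes downstream.

What the generator does *not* emulate: real query text semantics, document
retrieval and relevance, timing, or any dependence of the action choice on
position within the session beyond feasibility. Passing closed-loop and
recovery tests therefore show that the pipeline codes what the generator
wrote and that sampling is calibrated — they do not validate the taxonomy
against human coding of real logs, which were never released.

## The exact-count fixture builder

`fixture_from_counts()` reconstructs a log from published counts with no
randomness: given the 12-cell action-combination counts, session/search
totals, and optionally the position-by-action marginals, it spreads
session lengths as evenly as possible, allocates combinations to
first/middle/last slots (never `previous` at a first transition), deals
them round-robin so that every `previous` is preceded in its session by a
`new`, and realizes events with cycling (round-robin) choosers — including
the syntactic subtype, which the published tables do not break down.
`fixture_preset()` carries both arms' published counts; coding the
resulting logs reproduces the published profile, query, combination, and
position tables cell-for-cell, with 1398 and 585 transitions and 1135 and
396 consecutive pairs.

One degree of freedom is deliberately left open: the within-session
*ordering* of actions, which the published marginals do not determine.
The consecutive-pair table of a fixture log is therefore a valid but not
unique realization; pair-level statistics on published pair counts should
take those counts directly as inputs. The builder also mints profile
labels on demand rather than capping at six per arm: the coding depends
only on label identity and history, and a hard cap of six would make long
all-new-profile sessions unrealizable.

## Numerical and degenerate-input choices

* Chi-square requires strictly positive row and column totals; a zero
  margin raises a degenerate-table error rather than returning `NaN`.
  Rows absent from a log (structural zeros in the 12- or 16-row tables)
  are dropped before the test, so degrees of freedom reflect observed
  categories.
* `two_proportion_z()` errors on zero standard error (both proportions 0
  or both 1) instead of dividing by zero.
* Wilson bounds are computed in full precision and rounded only at
  display: percentages to 1 decimal, CI bounds to 2, z and chi-square
  to 2.
* Single-arm logs produce all tables; between-arm tests are skipped with
  an explicit notice rather than an error.
* Empty logs and transition-free logs (all sessions of one search) are
  errors at `full_report()`, not silent empties.
* Test problem sizes: the closed-loop suite checks ten seeds of roughly a
  thousand transitions each and one run of about five thousand for
  frequency recovery, which keeps the whole suite in the low minutes while
  leaving binomial standard errors small enough for 3-SE checks to bind.

## Known limitations

* The taxonomy is monolingual and literal: no spelling correction, no
  synonym or ontology expansion, so `heart attack` → `myocardial
  infarction` codes as semantic replacement, never as equivalence.
* The variant relation is intentionally simple; exotic inflections or
  short-word spelling variants (length < 4) fall through to semantic.
* Whether the original coding was manual or automated is unknown; this
  package is one fully specified, reproducible operationalization of the
  published definitions.
* The fixture builder targets the published marginals only; higher-order
  session structure (e.g. the joint distribution of positions and
  actions, or pair sequences) is a constructed realization, not data.
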