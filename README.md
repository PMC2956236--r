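# searchcode

Coding and analysis of clinician search-session logs.

When clinicians answer a clinical question with an online retrieval system,
they rarely stop at one search: they reformulate keywords, switch search
profiles (an information resource such as PubMed, or a clinical task such as
*diagnosis*), and try again. The sequence of searches one clinician submits
for one question is a **search session**, and each ordered pair of
consecutive searches is a **transition** — the unit of analysis here.
`searchcode` turns raw two-arm search-event logs into coded transitions and
the contingency-table statistics that compare search behavior between a
resource-based and a task-based system: breadth-first behavior (switch
profiles, keep the query) versus depth-first behavior (keep the profile,
rework the query).

## What gets coded

Each transition receives:

* a **profile code** — `same` (repeat of the immediately preceding profile),
  `previous` (used earlier in the session, not immediately preceding), or
  `new` (first use in the session);
* a **query code** — `none`, `syntactic_only`, `semantic_only`, or
  `syntactic_and_semantic`, where a *syntactic* reformulation changes
  surface form only (five sub-detectors: capitalization `IVF → ivf`, word
  order `asthma diagnosis → diagnosis asthma`, conjunctions `AND/OR/NOT`,
  spacing/grouping `heart-attack → heart attack`, typographic variants
  `apple → apples`, `behaviour → behavior`) and a *semantic* reformulation
  adds, removes, or replaces content keywords;
* the 4-way **action category** (no change / query only / profile only /
  both) and a **position label** (first / middle / last transition of the
  session).

Statistics on the resulting arm-by-category tables:

* Pearson chi-square test of independence,
  `X² = Σ (O − E)² / E`, `E = row total × column total / grand total`;
* Wilson score interval for each cell proportion,
  center `(p + z²/2n) / (1 + z²/n)`,
  half-width `z √(p(1−p)/n + z²/4n²) / (1 + z²/n)`;
* unpooled two-proportion z-test per table row,
  `z = (p₁ − p₂) / √(p₁(1−p₁)/n₁ + p₂(1−p₂)/n₂)`.

Because the original study logs were never released, the package ships a
synthetic-log generator (`behavior_spec()` + `generate_study_log()`) whose
realized edits are verified against the classifier (closed loop), and a
deterministic fixture builder (`fixture_from_counts()`) that reconstructs a
log from published contingency-table counts exactly.

## Worked example

```r
library(searchcode)

## classify one reformulation: case flip + added keyword
classify_query_reformulation(
  c(disease = "asthma child",        drug = "", symptom = "", other = ""),
  c(disease = "Asthma child spacer", drug = "", symptom = "", other = ""))
#> <query_code> syntactic_and_semantic { capitalization }

## generate a depth-first (task-arm style) synthetic log and summarize it
log <- generate_study_log(behavior_spec("task", n_participants = 4, seed = 42))
summary(log)
#> Study log: 32 sessions, 88 searches, 56 codable transitions
#>   arm sessions searches transitions
#>  task       32       88          56

## the statistics, on the published next-profile-action counts
tab <- matrix(c(557, 379, 202, 55, 639, 151), nrow = 3, byrow = TRUE,
              dimnames = list(c("same", "previous", "new"),
                              c("resource", "task")))
pearson_chi_square(tab)
#> chi-square(2) = 103.45, p <.001
wilson_interval(557, 1398)
#>      low     high
#> 37.30750 42.43343
two_proportion_z(401, 1398, 54, 585)
#> diff = 19.5 pp, z = 11.43, p <.001
```

The chi-square says the next-profile-action mix differs between arms; the
Wilson interval brackets the resource-arm `same` proportion (39.8%, 95% CI
37.31–42.43); the z-test says resource-arm users were 19.5 percentage points
more likely to move to a new profile without touching their keywords — the
breadth-first signature.

`full_report(log)` runs the whole pipeline on a two-arm log and
`write_report()` emits `table3.csv` … `table7.csv` plus a readable
`report.txt`. A command-line front end lives at `inst/cli/searchcode.R`
(`code`, `stats`, `simulate` subcommands).

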