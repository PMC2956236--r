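Package: searchcode
Title: Coding and Analysis of Clinician Search-Session Logs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Codes consecutive-search transitions in clinician search-session
    logs by profile selection (same, previously used, or new profile) and by
    query-reformulation type (syntactic and/or semantic keyword changes, with
    five syntactic sub-detectors: capitalization, word order, conjunctions,
    spacing, typographic variants), aggregates coded transitions into two-arm
    contingency tables, and computes Pearson chi-square tests, Wilson score
    intervals, and unpooled two-proportion z-tests. Includes a synthetic
    search-log generator with configurable behavioral structure
    (breadth-first versus depth-first search strategies) and a deterministic
    fixture builder that reconstructs logs from published contingency-table
    counts, so every pipeline stage is testable without access to raw study
    logs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
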