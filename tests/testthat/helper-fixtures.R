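# shared helpers: tiny log builders and memoized published-table fixtures

kw <- function(disease = "", drug = "", symptom = "", other = "") {
  c(disease = disease, drug = drug, symptom = symptom, other = other)
}

# one-session event data frame -> study_log
make_session_log <- function(profiles, disease = NULL, session_id = "s1",
                             arm = "resource", participant_id = "p1") {
  n <- length(profiles)
  if (is.null(disease)) disease <- rep("asthma", n)
  study_log(data.frame(
    participant_id = participant_id, session_id = session_id, arm = arm,
    seq_index = seq_len(n), profile = profiles,
    kw_disease = disease, kw_drug = "", kw_symptom = "", kw_other = "",
    stringsAsFactors = FALSE))
}

# drop generator-only attributes before field-for-field comparison
plain_events <- function(log) {
  df <- as.data.frame(log)
  attr(df, "intended") <- NULL
  class(df) <- "data.frame"
  df
}

# published-table fixture logs are expensive; build each arm once per run
.fixture_cache <- new.env(parent = emptyenv())

paper_fixture_log <- function(arm) {
  key <- paste0("fx_", arm)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- fixture_from_counts(fixture_preset(arm))
  .fixture_cache[[key]]
}

paper_fixture_both <- function() {
  if (is.null(.fixture_cache$both)) {
    .fixture_cache$both <- study_log(rbind(
      plain_events(paper_fixture_log("resource")),
      plain_events(paper_fixture_log("task"))))
  }
  .fixture_cache$both
}

paper_report <- function() {
  if (is.null(.fixture_cache$report))
    .fixture_cache$report <- full_report(paper_fixture_both())
  .fixture_cache$report
}

# brute-force Pearson chi-square: explicit double loop over cells
chisq_oracle <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- rs[i] * cs[j] / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  list(statistic = unname(stat),
       df = (nrow(counts) - 1L) * (ncol(counts) - 1L))
}

random_small_table <- function() {
  repeat {
    r <- sample(2:5, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, lambda = sample(3:40, 1)), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      dimnames(m) <- list(paste0("r", seq_len(r)), paste0("c", seq_len(c)))
      return(m)
    }
  }
}
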