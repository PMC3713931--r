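# shared fixture builders (everything generated in code; no stored data)

# minimal log directly from parallel vectors of matched events
log_from_events <- function(user, day, term, span = NULL) {
  query_log(data.frame(user = user, day = as.integer(day), term = term,
                       stringsAsFactors = FALSE), span = span)
}

# small dictionary used across IO tests
tiny_dict <- function() {
  term_dictionary(
    symptoms = c("nausea", "diplopia", "headache", "rash"),
    drugs = c("lipitor", "advil"),
    synonyms = c("feeling sick" = "nausea", "double vision" = "diplopia",
                 "sick to my stomach" = "nausea"),
    generic_map = c(lipitor = "atorvastatin"))
}

# independent oracle for term matching: scan every synonym with a plain
# word-boundary regex, no masking, no ordering
oracle_match <- function(q, dict) {
  qn <- paste0(" ", gsub("[^a-z0-9]+", " ", tolower(q)), " ")
  qn <- gsub(" {2,}", " ", qn)
  hits <- unname(dict$synonyms[vapply(names(dict$synonyms), function(s) {
    grepl(paste0(" ", s, " "), qn, fixed = TRUE)
  }, logical(1))])
  sort(unique(hits))
}

# simulator config for a small single-drug world with optional planted ADRs
small_world <- function(n_users = 2000, n_symptoms = 12, planted = character(),
                        multiplier = 5, adoption = 0.3, rate = 0.001,
                        seed = 42, ...) {
  symptoms <- stats::setNames(rep(rate, n_symptoms),
                              sprintf("s%02d", seq_len(n_symptoms)))
  eff <- if (length(planted)) {
    do.call(rbind, lapply(planted, function(s)
      adr_effect("druga", s, multiplier)))
  } else NULL
  sim_config(n_users = n_users, drugs = c(druga = adoption),
             symptoms = symptoms, effects = eff, seed = seed, ...)
}
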