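#' Built-in English stopword list
#'
#' Small fixed list used by [lexical_affinity_expansion()]; override by
#' passing your own vector.
#'
#' @return character vector.
#' @export
default_stopwords <- function() {
  c("a", "about", "after", "all", "an", "and", "are", "as", "at", "be",
    "but", "by", "can", "do", "for", "from", "had", "has", "have", "how",
    "i", "if", "in", "into", "is", "it", "its", "may", "more", "most",
    "my", "no", "not", "of", "on", "or", "over", "such", "than", "that",
    "the", "their", "then", "there", "they", "this", "to", "up", "was",
    "we", "what", "when", "which", "who", "will", "with", "you", "your")
}

.expansion_set <- function(df) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(symptom = character(), term = character(),
                     source = character(), score = numeric(),
                     rank = integer())
  }
  rownames(df) <- NULL
  structure(df, class = c("expansion_set", "data.frame"))
}

#' Vocabulary expansion from a click log
#'
#' For each symptom, selects the `k` query strings that most often led users
#' to click that symptom's reference page, excluding the canonical name
#' itself. Counts are aggregated over records before ranking, so the result
#' is invariant to record order; ties break lexicographically.
#'
#' @param clicks data.frame with columns `query`, `symptom` (canonical id of
#'   the clicked reference page) and `count` (positive integer).
#' @param k number of expansion terms to keep per symptom (default 2, the
#'   study design's choice).
#' @return An `expansion_set` data.frame: `symptom`, `term`, `source`
#'   (`"click"`), `score` (total clicks), `rank`.
#' @export
click_expansion <- function(clicks, k = 2) {
  stopifnot(k >= 1)
  if (is.null(clicks) || !nrow(clicks)) return(.expansion_set(NULL))
  need <- c("query", "symptom", "count")
  if (!all(need %in% names(clicks))) {
    stop("click log needs columns ", paste(need, collapse = ", "))
  }
  if (any(clicks$count < 1)) stop("click counts must be >= 1")
  q <- normalize_text(clicks$query)
  s <- normalize_text(clicks$symptom)
  agg <- stats::aggregate(list(score = as.numeric(clicks$count)),
                          by = list(symptom = s, term = q), FUN = sum)
  agg <- agg[agg$term != agg$symptom & nzchar(agg$term), , drop = FALSE]
  out <- do.call(rbind, lapply(split(agg, agg$symptom), function(d) {
    d <- d[order(-d$score, d$term), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  if (is.null(out)) return(.expansion_set(NULL))
  out$source <- "click"
  .expansion_set(out[order(out$symptom, out$rank),
                     c("symptom", "term", "source", "score", "rank")])
}

.doc_pairs <- function(tokens, window) {
  n <- length(tokens)
  if (n < 2) return(character())
  out <- character()
  for (i in seq_len(n - 1)) {
    jmax <- min(n, i + window)
    for (j in (i + 1):jmax) {
      if (tokens[i] == tokens[j]) next
      pair <- sort(c(tokens[i], tokens[j]))
      out <- c(out, paste(pair, collapse = " "))
    }
  }
  out
}

#' Vocabulary expansion from lexical affinities in a document corpus
#'
#' Stand-in for mining top web-search results: for each symptom, word pairs
#' co-occurring within `window` tokens (after stopword removal) are counted
#' across that symptom's documents, and the `k` most frequent pairs are
#' emitted as two-word phrases. Ties break lexicographically; a phrase equal
#' to the canonical symptom name is excluded.
#'
#' @param docs either a named list (symptom id -> character vector of
#'   documents) or a directory containing one `<symptom>.txt` file per
#'   symptom.
#' @param window co-occurrence window in tokens (default 5).
#' @param k pairs to keep per symptom (default 2).
#' @param stopwords words dropped before pairing.
#' @return An `expansion_set` data.frame with `source = "lexical"`.
#' @export
lexical_affinity_expansion <- function(docs, window = 5, k = 2,
                                       stopwords = default_stopwords()) {
  stopifnot(window >= 1, k >= 1)
  if (is.character(docs) && length(docs) == 1 && dir.exists(docs)) {
    files <- list.files(docs, pattern = "\\.txt$", full.names = TRUE)
    docs <- stats::setNames(
      lapply(files, function(f) readLines(f, warn = FALSE)),
      normalize_text(sub("\\.txt$", "", basename(files))))
  }
  if (!length(docs)) return(.expansion_set(NULL))
  rows <- lapply(names(docs), function(sym) {
    sym_n <- normalize_text(sym)
    counts <- table(unlist(lapply(docs[[sym]], function(d) {
      toks <- strsplit(normalize_text(d), " ", fixed = TRUE)[[1]]
      toks <- toks[nzchar(toks) & !toks %in% stopwords]
      .doc_pairs(toks, window)
    }), use.names = FALSE))
    counts <- counts[names(counts) != sym_n]
    if (!length(counts)) return(NULL)
    d <- data.frame(symptom = sym_n, term = names(counts),
                    source = "lexical", score = as.numeric(counts))
    d <- d[order(-d$score, d$term), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d
  })
  .expansion_set(do.call(rbind, rows))
}

#' Merge expansion terms into a term dictionary
#'
#' Adds each expansion term as a synonym of its symptom. A term already
#' mapped to a different canonical id in the base dictionary is kept as in
#' the base (the conflict is reported as a warning); base synonyms are never
#' removed.
#'
#' @param exp an `expansion_set` from [click_expansion()] or
#'   [lexical_affinity_expansion()] (or both, row-bound).
#' @param base a [term_dictionary()].
#' @return A new [term_dictionary()].
#' @export
build_synonym_map <- function(exp, base) {
  stopifnot(inherits(base, "term_dictionary"))
  if (is.null(exp) || !nrow(exp)) return(base)
  terms <- normalize_text(exp$term)
  targets <- normalize_text(exp$symptom)
  keep <- nzchar(terms)
  terms <- terms[keep]; targets <- targets[keep]
  syn <- base$synonyms
  conflicts <- character()
  for (i in seq_along(terms)) {
    existing <- if (terms[i] %in% names(syn)) syn[[terms[i]]] else NA_character_
    if (!is.na(existing)) {
      if (existing != targets[i]) conflicts <- c(conflicts, terms[i])
      next
    }
    if (!targets[i] %in% c(base$symptoms, base$drugs)) {
      stop("expansion targets unknown symptom: ", targets[i])
    }
    syn[terms[i]] <- targets[i]
  }
  if (length(conflicts)) {
    warning("expansion term(s) already mapped in base dictionary, base kept: ",
            paste(unique(conflicts), collapse = ", "))
  }
  extra <- syn[setdiff(names(syn), names(base$synonyms))]
  nonself <- base$synonyms[names(base$synonyms) != unname(base$synonyms)]
  term_dictionary(symptoms = base$symptoms, drugs = base$drugs,
                  synonyms = c(nonself, extra),
                  generic_map = base$generic_map)
}
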