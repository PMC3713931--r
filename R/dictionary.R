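#' Term dictionaries: canonical symptoms, drugs, synonyms and generics
#'
#' A term dictionary maps the many surface forms patients use in search
#' queries onto a fixed vocabulary of canonical symptom ids (the study design
#' targets the ~195 ICD-10 symptom terms that have a common-language reference
#' page) and drug brand names, optionally grouped into generics. Every
#' canonical name is also its own synonym, every synonym maps to exactly one
#' canonical id, and all ids are case-normalised.
#'
#' @param symptoms character vector of canonical symptom ids.
#' @param drugs character vector of canonical drug (brand) ids.
#' @param synonyms named character vector: `names()` are synonym strings,
#'   values are the canonical id each maps to. Canonical self-synonyms are
#'   added automatically.
#' @param generic_map named character vector mapping brand ids to generic ids;
#'   may cover only a subset of `drugs`.
#' @return An object of class `term_dictionary`: a list with elements
#'   `symptoms`, `drugs`, `synonyms` (named character, normalised synonym ->
#'   canonical id) and `generic_map`.
#' @export
#' @examples
#' d <- term_dictionary(symptoms = "nausea",
#'                      synonyms = c("feeling sick" = "nausea"))
#' match_terms("i keep feeling sick", d)
term_dictionary <- function(symptoms = character(), drugs = character(),
                            synonyms = NULL, generic_map = NULL) {
  symptoms <- unique(normalize_text(symptoms))
  drugs <- unique(normalize_text(drugs))
  symptoms <- symptoms[nzchar(symptoms)]
  drugs <- drugs[nzchar(drugs)]
  both <- intersect(symptoms, drugs)
  if (length(both)) {
    stop("ids used as both symptom and drug: ", paste(both, collapse = ", "))
  }
  canon <- c(symptoms, drugs)
  syn <- stats::setNames(canon, canon)  # self-synonyms
  if (length(synonyms)) {
    keys <- normalize_text(names(synonyms))
    vals <- normalize_text(unname(synonyms))
    bad <- !vals %in% canon
    if (any(bad)) {
      stop("synonyms map to unknown canonical ids: ",
           paste(unique(vals[bad]), collapse = ", "))
    }
    for (i in seq_along(keys)) {
      k <- keys[i]
      if (!nzchar(k)) next
      existing <- if (k %in% names(syn)) syn[[k]] else NA_character_
      if (!is.na(existing) && existing != vals[i]) {
        stop("conflicting synonym '", k, "': maps to both '", existing,
             "' and '", vals[i], "'")
      }
      syn[k] <- vals[i]
    }
  }
  gm <- character()
  if (length(generic_map)) {
    gm <- stats::setNames(normalize_text(unname(generic_map)),
                          normalize_text(names(generic_map)))
    gm <- gm[nzchar(gm)]
    unknown <- setdiff(names(gm), drugs)
    if (length(unknown)) {
      stop("generic_map covers unknown drugs: ", paste(unknown, collapse = ", "))
    }
  }
  structure(list(symptoms = sort(symptoms), drugs = sort(drugs),
                 synonyms = syn, generic_map = gm),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("Term dictionary: ", length(x$symptoms), " symptoms, ",
      length(x$drugs), " drugs, ", length(x$synonyms),
      " synonym keys, ", length(x$generic_map),
      " brand->generic mappings\n", sep = "")
  invisible(x)
}

#' Read a term dictionary from CSV
#'
#' The file must have columns `canonical`, `synonym`, `kind`
#' (`symptom` or `drug`) and `generic` (empty or `-` for none). Rows with the
#' same canonical id accumulate synonyms; a synonym string appearing under two
#' different canonical ids is a validation error.
#'
#' @param path CSV file path.
#' @return A [term_dictionary()].
#' @export
load_term_dictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("canonical", "synonym", "kind", "generic")
  if (!all(need %in% names(df))) {
    stop("dictionary must have columns ", paste(need, collapse = ", "))
  }
  if (!nrow(df)) return(term_dictionary())
  kind <- tolower(trimws(df$kind))
  bad <- which(!kind %in% c("symptom", "drug"))
  if (length(bad)) {
    stop("malformed dictionary row at line ", bad[1] + 1L,
         ": kind must be 'symptom' or 'drug', got '", df$kind[bad[1]], "'")
  }
  blank <- which(!nzchar(normalize_text(df$canonical)))
  if (length(blank)) {
    stop("malformed dictionary row at line ", blank[1] + 1L,
         ": empty canonical id")
  }
  canon <- normalize_text(df$canonical)
  synkey <- normalize_text(df$synonym)
  # conflicting synonym rows: same key, different canonical
  use <- nzchar(synkey)
  tab <- tapply(canon[use], synkey[use], function(v) length(unique(v)))
  if (any(tab > 1)) {
    stop("conflicting synonym(s): ",
         paste(names(tab)[tab > 1], collapse = ", "),
         " mapped to more than one canonical id")
  }
  gen <- normalize_text(df$generic)
  gen[gen %in% c("", "-", "na")] <- NA_character_
  gm <- NULL
  has_gen <- kind == "drug" & !is.na(gen)
  if (any(has_gen)) {
    gm <- tapply(gen[has_gen], canon[has_gen], function(v) {
      u <- unique(v)
      if (length(u) > 1) stop("brand mapped to multiple generics: ",
                              paste(u, collapse = ", "))
      u
    })
    gm <- stats::setNames(as.character(gm), names(gm))
  }
  term_dictionary(symptoms = unique(canon[kind == "symptom"]),
                  drugs = unique(canon[kind == "drug"]),
                  synonyms = stats::setNames(canon[use], synkey[use]),
                  generic_map = gm)
}

#' Write a term dictionary to CSV
#'
#' Inverse of [load_term_dictionary()].
#'
#' @param dict a [term_dictionary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_term_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "term_dictionary"))
  canon <- unname(dict$synonyms)
  kind <- ifelse(canon %in% dict$drugs, "drug", "symptom")
  gen <- ifelse(kind == "drug" & canon %in% names(dict$generic_map),
                dict$generic_map[canon], "-")
  df <- data.frame(canonical = canon, synonym = names(dict$synonyms),
                   kind = kind, generic = gen, row.names = NULL)
  df <- df[order(df$canonical, df$synonym), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.match_one <- function(norm, keys, canon) {
  if (!nzchar(norm)) return(character())
  padded <- paste0(" ", norm, " ")
  hits <- character()
  for (i in seq_along(keys)) {
    pat <- paste0(" ", keys[i], " ")
    repeat {
      pos <- regexpr(pat, padded, fixed = TRUE)
      if (pos < 0) break
      hits <- c(hits, canon[i])
      # mask the matched span (keep inner spaces) so embedded shorter
      # synonyms cannot re-match inside it
      seg <- substr(padded, pos + 1L, pos + nchar(keys[i]))
      substr(padded, pos + 1L, pos + nchar(keys[i])) <- gsub("[^ ]", "\x01", seg)
    }
  }
  sort(unique(hits))
}

#' Map raw query text to canonical dictionary ids
#'
#' Matching is exact substring on normalised text (lower case, punctuation to
#' spaces) at word boundaries. Synonyms are tried longest-first and a matched
#' span is consumed, so a multiword synonym such as "double vision" wins over
#' any unigram embedded in it; separate occurrences elsewhere in the query
#' still match. No match yields an empty set.
#'
#' @param x character vector of raw queries.
#' @param dict a [term_dictionary()].
#' @return For a single query, a character vector of canonical ids (sorted,
#'   unique). For longer input, a list of such vectors.
#' @export
#' @examples
#' d <- term_dictionary(symptoms = c("diplopia", "nausea"), drugs = "lipitor",
#'                      synonyms = c("double vision" = "diplopia"))
#' match_terms("Double Vision help", d)   # "diplopia"
#' match_terms("lipitor nausea", d)       # both ids
match_terms <- function(x, dict) {
  stopifnot(inherits(dict, "term_dictionary"))
  keys <- names(dict$synonyms)
  ord <- order(-nchar(keys), keys)
  keys <- keys[ord]
  canon <- unname(dict$synonyms)[ord]
  norms <- normalize_text(x)
  out <- lapply(norms, .match_one, keys = keys, canon = canon)
  if (length(x) == 1L) out[[1L]] else out
}
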