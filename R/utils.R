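# internal helpers shared across modules

#' Normalise free text for term matching
#'
#' Lower-cases, maps punctuation to spaces, collapses whitespace and trims.
#' All dictionary ids and synonym keys are stored in this normal form, so
#' matching is exact-substring on normalised text (no stemming).
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @keywords internal
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" {2,}", " ", x))
}

# FNV-1a 32-bit hash, pure R. Used only by the optional user-id anonymisation
# hook. bitwXor only handles 32-bit signed integers, so the xor is done on the
# low byte and the multiply on split 16-bit halves to stay inside double
# precision.
.fnv1a32_one <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(enc2utf8(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    hl <- h %% 65536
    hh <- (h - hl) / 65536
    h <- ((hh * prime) %% 65536) * 65536 + hl * prime
    h <- h %% 4294967296
  }
  hl <- h %% 65536
  sprintf("h%04x%04x", as.integer((h - hl) / 65536), as.integer(hl))
}

#' One-way hash of user identifiers
#'
#' Optional anonymisation hook applied at ingest: user ids are replaced by a
#' 32-bit FNV-1a hash so the mapping cannot be inverted (beyond brute force).
#' Off by default everywhere; results are unaffected because downstream code
#' only ever groups by the opaque id.
#'
#' @param ids character vector of user identifiers.
#' @return character vector of hashed identifiers.
#' @export
#' @examples
#' hash_user_ids(c("alice", "bob"))
hash_user_ids <- function(ids) {
  vapply(as.character(ids), .fnv1a32_one, character(1), USE.NAMES = FALSE)
}

# Derive a secondary seed below 2^31 from a base seed and an offset.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e9) * 2 + 1 + offset) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
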