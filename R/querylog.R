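#' Query-log container
#'
#' A query log is the raw observational substrate: one record per
#' (user, day, query), with queries already matched to canonical dictionary
#' ids. Internally it is a long data frame with one row per
#' (query event, matched term); an event matching k terms occupies k rows
#' sharing an `event` id, and an event matching nothing keeps a single row
#' with `term = NA` (it still defines the user's observed history span).
#' Days are integer indices since the log origin, which avoids calendar and
#' timezone ambiguity in all downstream logic.
#'
#' @param events data.frame with columns `user` (character), `day`
#'   (integer >= 0), `term` (character or NA) and optionally `event`
#'   (integer record id) and `raw` (original query text).
#' @param span integer number of days covered; defaults to `max(day) + 1`.
#' @param origin a `Date`; day 0 corresponds to this date on write.
#' @param n_skipped number of input records dropped at parse time.
#' @return An object of class `query_log`: list with elements `events`,
#'   `span`, `origin`, `n_records`, `n_skipped`.
#' @export
query_log <- function(events, span = NULL, origin = as.Date("2000-01-01"),
                      n_skipped = 0L) {
  stopifnot(is.data.frame(events))
  need <- c("user", "day", "term")
  if (!all(need %in% names(events))) {
    stop("events must have columns ", paste(need, collapse = ", "))
  }
  events$user <- as.character(events$user)
  events$day <- as.integer(events$day)
  events$term <- as.character(events$term)
  if (is.null(events$event)) events$event <- seq_len(nrow(events))
  if (nrow(events) && any(is.na(events$day) | events$day < 0)) {
    stop("event days must be non-negative integers")
  }
  span <- as.integer(span %||% if (nrow(events)) max(events$day) + 1L else 0L)
  if (nrow(events) && any(events$day >= span)) {
    stop("event day outside [0, span)")
  }
  o <- order(events$user, events$day, events$event)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, span = span, origin = origin,
                 n_records = length(unique(events$event)),
                 n_skipped = as.integer(n_skipped)),
            class = "query_log")
}

#' @export
print.query_log <- function(x, ...) {
  cat("Query log: ", x$n_records, " records from ",
      length(unique(x$events$user)), " users over ", x$span, " days",
      if (x$n_skipped > 0) paste0(" (", x$n_skipped, " records skipped)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-user observed history spans
#'
#' @param log a [query_log()].
#' @return data.frame with one row per user: `user`, `first_day`, `last_day`,
#'   `n_events` (number of query records, matched or not).
#' @export
user_spans <- function(log) {
  stopifnot(inherits(log, "query_log"))
  ev <- log$events
  if (!nrow(ev)) {
    return(data.frame(user = character(), first_day = integer(),
                      last_day = integer(), n_events = integer()))
  }
  u <- factor(ev$user)
  first <- tapply(ev$day, u, min)
  last <- tapply(ev$day, u, max)
  nev <- tapply(ev$event, u, function(e) length(unique(e)))
  data.frame(user = levels(u), first_day = as.integer(first),
             last_day = as.integer(last), n_events = as.integer(nev),
             row.names = NULL)
}

#' Parse raw query records into a query log
#'
#' Records with unparseable dates are skipped (counted and reported via a
#' message). Queries are matched to dictionary terms with [match_terms()];
#' records matching nothing are retained with `term = NA` so that they still
#' contribute to the user's observed history span. Day indices count from the
#' earliest parseable date in the input.
#'
#' @param records data.frame with columns `user_id`, `date` (ISO-8601 string
#'   or `Date`) and `query`.
#' @param dict a [term_dictionary()].
#' @param hash_users if `TRUE`, user ids are one-way hashed at ingest via
#'   [hash_user_ids()]. Off by default.
#' @return A [query_log()].
#' @export
parse_query_log <- function(records, dict, hash_users = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("user_id", "date", "query")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  if (!nrow(records)) {
    return(query_log(data.frame(user = character(), day = integer(),
                                term = character(), event = integer(),
                                raw = character())))
  }
  dates <- suppressWarnings(as.Date(as.character(records$date),
                                    format = "%Y-%m-%d"))
  skipped <- sum(is.na(dates))
  if (skipped > 0) {
    message(skipped, " record(s) skipped: unparseable date")
  }
  keep <- !is.na(dates)
  records <- records[keep, , drop = FALSE]
  dates <- dates[keep]
  if (!nrow(records)) {
    return(query_log(data.frame(user = character(), day = integer(),
                                term = character(), event = integer(),
                                raw = character()),
                     n_skipped = skipped))
  }
  origin <- min(dates)
  day <- as.integer(dates - origin)
  users <- as.character(records$user_id)
  if (hash_users) users <- hash_user_ids(users)
  # match unique queries once, then expand
  uq <- unique(as.character(records$query))
  matched <- match_terms(uq, dict)
  if (length(uq) == 1L) matched <- list(matched)
  terms <- matched[match(as.character(records$query), uq)]
  k <- vapply(terms, length, integer(1))
  reps <- pmax(k, 1L)
  idx <- rep(seq_len(nrow(records)), reps)
  term <- unlist(lapply(terms, function(t) if (length(t)) t else NA_character_),
                 use.names = FALSE)
  ev <- data.frame(user = users[idx], day = day[idx], term = term,
                   event = idx, raw = as.character(records$query)[idx],
                   stringsAsFactors = FALSE)
  query_log(ev, origin = origin, n_skipped = skipped)
}

#' Read a query log from a TSV file
#'
#' Expects tab-separated columns `user_id`, `date` (ISO-8601) and `query`,
#' with a header line. Gzip-compressed files are handled transparently.
#'
#' @inheritParams parse_query_log
#' @param path TSV(.gz) file path.
#' @return A [query_log()].
#' @export
read_query_log <- function(path, dict, hash_users = FALSE) {
  if (!file.exists(path)) stop("query log not found: ", path)
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  parse_query_log(df, dict, hash_users = hash_users)
}

#' Write a query log to a TSV file
#'
#' One line per query record. Where the original raw query text was kept it
#' is written back verbatim; otherwise the matched canonical terms are
#' written space-separated (canonical ids are self-synonyms, so re-parsing
#' with the same dictionary reproduces the same matched terms).
#'
#' @param log a [query_log()].
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_query_log <- function(log, path) {
  stopifnot(inherits(log, "query_log"))
  ev <- log$events
  if (nrow(ev)) {
    sp <- split(seq_len(nrow(ev)), ev$event)
    rows <- vapply(sp, `[`, integer(1), 1L)  # first row of each event
    qtext <- vapply(sp, function(i) {
      if (!is.null(ev$raw) && !is.na(ev$raw[i[1]])) return(ev$raw[i[1]])
      tt <- ev$term[i]
      tt <- sort(tt[!is.na(tt)])
      paste(tt, collapse = " ")
    }, character(1))
    out <- data.frame(user_id = ev$user[rows],
                      date = format(log$origin + ev$day[rows]),
                      query = qtext, stringsAsFactors = FALSE)
    out <- out[order(out$user_id, out$date), ]
  } else {
    out <- data.frame(user_id = character(), date = character(),
                      query = character())
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
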