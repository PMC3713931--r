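#' Assign Day Zero to every user in a query log
#'
#' For users who searched for the drug at least once, Day Zero is the day of
#' their first drug query; for all other users it is the midpoint of their
#' observed query history, `floor((first_day + last_day) / 2)`. The unexposed
#' arm normalises environmental effects (e.g. seasonal symptom load) out of
#' the before/after comparison.
#'
#' @param log a [query_log()].
#' @param drug canonical drug id.
#' @return data.frame with one row per user: `user`, `day_zero`, `exposed`.
#' @export
assign_day_zero <- function(log, drug) {
  stopifnot(inherits(log, "query_log"))
  drug <- normalize_text(drug)
  sp <- user_spans(log)
  if (!nrow(sp)) {
    return(data.frame(user = character(), day_zero = integer(),
                      exposed = logical()))
  }
  ev <- log$events
  dd <- ev[!is.na(ev$term) & ev$term == drug, c("user", "day")]
  first_drug <- if (nrow(dd)) tapply(dd$day, dd$user, min) else
    stats::setNames(integer(), character())
  hit <- match(sp$user, names(first_drug))
  exposed <- !is.na(hit)
  dz <- (sp$first_day + sp$last_day) %/% 2L
  dz[exposed] <- as.integer(first_drug[hit[exposed]])
  data.frame(user = sp$user, day_zero = as.integer(dz), exposed = exposed)
}

#' Most frequently queried symptoms among a drug's users
#'
#' Candidate ADRs for a drug are restricted to the `k` symptoms most queried
#' by the drug-exposed users (before plus after Day Zero); ties break
#' lexicographically.
#'
#' @inheritParams assign_day_zero
#' @param dz optional precomputed [assign_day_zero()] result.
#' @param k number of symptoms to keep (default 50, the design's choice).
#' @param symptoms character vector delimiting the symptom universe; by
#'   default every matched term in the log other than `drug` (pass the
#'   dictionary's symptom set to exclude other drugs).
#' @return character vector of symptom ids, most queried first.
#' @export
select_top_symptoms <- function(log, drug, dz = NULL, k = 50, symptoms = NULL) {
  stopifnot(inherits(log, "query_log"), k >= 1)
  drug <- normalize_text(drug)
  if (is.null(dz)) dz <- assign_day_zero(log, drug)
  exp_users <- dz$user[dz$exposed]
  if (!length(exp_users)) {
    warning("no users searched for drug '", drug, "'")
    return(character())
  }
  ev <- log$events
  if (is.null(symptoms)) {
    symptoms <- setdiff(unique(ev$term[!is.na(ev$term)]), drug)
  } else {
    symptoms <- normalize_text(symptoms)
  }
  sel <- !is.na(ev$term) & ev$term %in% symptoms & ev$user %in% exp_users
  if (!any(sel)) return(character())
  counts <- table(ev$term[sel])
  ord <- order(-as.numeric(counts), names(counts))
  utils::head(names(counts)[ord], k)
}

#' Build the drug-symptom contingency table
#'
#' Counts every symptom-query event into one of four cells by whether the
#' querying user searched for the drug and whether the event fell before or
#' after that user's Day Zero. By default an event exactly on Day Zero
#' counts as "after": a drug and a reaction to it are often first queried the
#' same day, and discarding those events would drop the most informative ones
#' (`boundary = "before"` flips the convention).
#'
#' @inheritParams select_top_symptoms
#' @param symptom canonical symptom id.
#' @param boundary `"after"` (default) or `"before"`: which side of the table
#'   an event exactly on Day Zero falls on.
#' @param dedup if `TRUE`, count at most one query per user, symptom and day
#'   (burst robustness); by default every query event counts.
#' @return 2x2 integer matrix, rows `before`/`after`, columns
#'   `no`/`yes` (user queried for the drug): `N11 = [before, no]`,
#'   `N12 = [before, yes]`, `N21 = [after, no]`, `N22 = [after, yes]`.
#' @export
build_contingency <- function(log, drug, symptom, dz = NULL,
                              boundary = c("after", "before"),
                              dedup = FALSE) {
  stopifnot(inherits(log, "query_log"))
  boundary <- match.arg(boundary)
  drug <- normalize_text(drug)
  symptom <- normalize_text(symptom)
  if (is.null(dz)) dz <- assign_day_zero(log, drug)
  ev <- log$events
  ev <- ev[!is.na(ev$term) & ev$term == symptom, , drop = FALSE]
  if (dedup && nrow(ev)) ev <- ev[!duplicated(ev[c("user", "day")]), ]
  m <- matrix(0L, 2, 2,
              dimnames = list(period = c("before", "after"),
                              drug = c("no", "yes")))
  if (!nrow(ev)) return(m)
  i <- match(ev$user, dz$user)
  expo <- dz$exposed[i]
  aft <- if (boundary == "after") ev$day >= dz$day_zero[i] else
    ev$day > dz$day_zero[i]
  m[1, 1] <- sum(!expo & !aft)
  m[1, 2] <- sum(expo & !aft)
  m[2, 1] <- sum(!expo & aft)
  m[2, 2] <- sum(expo & aft)
  m
}

#' The query-log reaction score (QLRS) of a contingency table
#'
#' Pearson's goodness-of-fit chi-square statistic, without continuity
#' correction: `sum((O - E)^2 / E)` with expected counts from the row and
#' column margins under independence. A table with any zero margin scores 0
#' (no association is estimable); an all-zero table is an error. The score is
#' unsigned; the direction of the association is carried separately as
#' `sign(N22 - E22)`, positive when exposed users queried the symptom after
#' Day Zero more than independence predicts.
#'
#' @param tab 2x2 non-negative matrix as from [build_contingency()].
#' @return list with `statistic` (the QLRS), `direction` (-1, 0 or +1) and
#'   `expected` (2x2 matrix, NULL for degenerate margins).
#' @export
#' @examples
#' qlrs_score(matrix(c(10, 30, 20, 40), 2, 2))$statistic  # 50/63
qlrs_score <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == 2)) stop("tab must be a 2x2 matrix")
  if (any(is.na(tab)) || any(tab < 0)) stop("cells must be non-negative")
  n <- sum(tab)
  if (n == 0) stop("empty table")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = 0, direction = 0L, expected = NULL))
  }
  e <- outer(rs, cs) / n
  list(statistic = sum((tab - e)^2 / e),
       direction = as.integer(sign(tab[2, 2] - e[2, 2])),
       expected = e)
}

#' Rank candidate adverse drug reactions for a drug
#'
#' The main fitting function: assigns Day Zero to every user, keeps the
#' `top_k` most-queried symptoms among the drug's users, builds each
#' symptom's before/after x exposed/unexposed contingency table and scores it
#' with the QLRS chi-square. The returned object holds all scored symptoms
#' sorted by decreasing score; candidate-ADR output additionally keeps only
#' positive-direction symptoms (an increase after Day Zero), since the
#' chi-square also fires on decreases.
#'
#' @inheritParams build_contingency
#' @param dictionary optional [term_dictionary()]; its symptom set delimits
#'   the symptom universe.
#' @param symptoms explicit symptom universe (overrides `dictionary`).
#' @param top_k symptoms to score (default 50).
#' @param positive_only default direction filter applied by
#'   [candidate_adrs()] and printing; scores for all directions are kept in
#'   the object (rank correlations against report databases use them all).
#' @return An object of class `qlrs`: list with `drug`, `scores` (data.frame
#'   `symptom`, `qlrs`, `direction`, `N11`, `N12`, `N21`, `N22`, sorted by
#'   decreasing score), `n_users`, `n_exposed`, `top_k`, `positive_only`,
#'   `boundary`, `day_zero` and `call`.
#' @seealso [candidate_adrs()], [compare_rankings()], [greedy_mdadr()]
#' @export
qlrs <- function(log, drug, dictionary = NULL, symptoms = NULL, top_k = 50,
                 positive_only = TRUE, boundary = c("after", "before"),
                 dedup = FALSE) {
  stopifnot(inherits(log, "query_log"))
  boundary <- match.arg(boundary)
  drug <- normalize_text(drug)
  if (is.null(symptoms) && !is.null(dictionary)) {
    stopifnot(inherits(dictionary, "term_dictionary"))
    symptoms <- dictionary$symptoms
  }
  dz <- assign_day_zero(log, drug)
  if (!any(dz$exposed)) stop("no users searched for drug '", drug, "'")
  top <- select_top_symptoms(log, drug, dz = dz, k = top_k,
                             symptoms = symptoms)
  if (!length(top)) {
    warning("no symptom queries among exposed users of '", drug, "'")
    return(structure(list(drug = drug,
                          scores = data.frame(symptom = character(),
                                              qlrs = numeric(),
                                              direction = integer(),
                                              N11 = integer(), N12 = integer(),
                                              N21 = integer(), N22 = integer()),
                          n_users = nrow(dz), n_exposed = sum(dz$exposed),
                          top_k = top_k, positive_only = positive_only,
                          boundary = boundary, day_zero = dz,
                          call = match.call()),
                     class = "qlrs"))
  }
  ev <- log$events
  ev <- ev[!is.na(ev$term) & ev$term %in% top, , drop = FALSE]
  if (dedup && nrow(ev)) {
    ev <- ev[!duplicated(ev[c("user", "term", "day")]), ]
  }
  i <- match(ev$user, dz$user)
  expo <- dz$exposed[i]
  aft <- if (boundary == "after") ev$day >= dz$day_zero[i] else
    ev$day > dz$day_zero[i]
  f <- factor(ev$term, levels = top)
  n11 <- as.integer(tapply(!expo & !aft, f, sum, default = 0L))
  n12 <- as.integer(tapply(expo & !aft, f, sum, default = 0L))
  n21 <- as.integer(tapply(!expo & aft, f, sum, default = 0L))
  n22 <- as.integer(tapply(expo & aft, f, sum, default = 0L))
  tot <- n11 + n12 + n21 + n22
  r1 <- n11 + n12; r2 <- n21 + n22
  c1 <- n11 + n21; c2 <- n12 + n22
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- numeric(length(top))
  dir <- integer(length(top))
  e11 <- r1 * c1 / tot; e12 <- r1 * c2 / tot
  e21 <- r2 * c1 / tot; e22 <- r2 * c2 / tot
  stat[ok] <- ((n11 - e11)^2 / e11 + (n12 - e12)^2 / e12 +
                 (n21 - e21)^2 / e21 + (n22 - e22)^2 / e22)[ok]
  dir[ok] <- as.integer(sign(n22 - e22))[ok]
  scores <- data.frame(symptom = top, qlrs = stat, direction = dir,
                       N11 = n11, N12 = n12, N21 = n21, N22 = n22)
  scores <- scores[order(-scores$qlrs, scores$symptom), , drop = FALSE]
  rownames(scores) <- NULL
  structure(list(drug = drug, scores = scores,
                 n_users = nrow(dz), n_exposed = sum(dz$exposed),
                 top_k = top_k, positive_only = positive_only,
                 boundary = boundary, day_zero = dz,
                 call = match.call()),
            class = "qlrs")
}

#' Candidate ADR list from a QLRS fit
#'
#' @param object a [qlrs()] fit.
#' @param threshold minimum QLRS to report (default 0; use
#'   `qchisq(0.95, 1) = 3.841` for the nominal p < .05 screen).
#' @return data.frame of positive-direction symptoms above the threshold,
#'   sorted by decreasing score.
#' @export
candidate_adrs <- function(object, threshold = 0) {
  stopifnot(inherits(object, "qlrs"))
  s <- object$scores
  s <- s[s$direction > 0 & s$qlrs >= threshold, , drop = FALSE]
  rownames(s) <- NULL
  s
}

#' @export
print.qlrs <- function(x, n = 10, ...) {
  cat("QLRS fit for drug '", x$drug, "': ", x$n_exposed, "/", x$n_users,
      " users exposed, ", nrow(x$scores), " symptoms scored\n", sep = "")
  s <- if (x$positive_only) candidate_adrs(x) else x$scores
  cat(if (x$positive_only) "Top candidate ADRs (positive direction):\n"
      else "Top symptoms:\n")
  print(utils::head(s, n), digits = 4)
  invisible(x)
}

#' @export
summary.qlrs <- function(object, threshold = stats::qchisq(0.95, 1), ...) {
  s <- object$scores
  structure(list(drug = object$drug, n_users = object$n_users,
                 n_exposed = object$n_exposed, n_scored = nrow(s),
                 threshold = threshold,
                 n_significant = sum(s$qlrs > threshold),
                 n_positive = sum(s$direction > 0),
                 n_sig_positive = sum(s$qlrs > threshold & s$direction > 0),
                 scores = s),
            class = "summary.qlrs")
}

#' @export
print.summary.qlrs <- function(x, ...) {
  cat("QLRS fit for drug '", x$drug, "'\n", sep = "")
  cat("  users: ", x$n_users, " (", x$n_exposed, " exposed)\n", sep = "")
  cat("  symptoms scored: ", x$n_scored, "\n", sep = "")
  cat("  scores above chi-square(1) cutoff ", format(x$threshold, digits = 4),
      ": ", x$n_significant, " (", x$n_sig_positive,
      " with positive direction)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.qlrs <- function(x, row.names = NULL, optional = FALSE, ...) {
  s <- x$scores
  s$drug <- x$drug
  s[, c("drug", "symptom", "qlrs", "direction",
        "N11", "N12", "N21", "N22")]
}

#' @export
plot.qlrs <- function(x, n = 20, ...) {
  s <- utils::head(x$scores, n)
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(s$qlrs), names.arg = rev(s$symptom), horiz = TRUE,
                    las = 1, xlab = "QLRS (chi-square)",
                    col = ifelse(rev(s$direction) > 0, "firebrick", "grey70"),
                    main = paste("Candidate ADRs:", x$drug), ...)
  graphics::abline(v = stats::qchisq(0.95, 1), lty = 2)
  invisible(x)
}

#' Aggregate brand-level contingency tables into generics
#'
#' Different brand versions of the same generic drug are expected to share
#' ADRs; summing their contingency tables cell-wise before scoring focuses
#' the analysis on the active ingredient and pools the data.
#'
#' @param tables named list of 2x2 matrices (one per brand, all computed
#'   against the same symptom).
#' @param generic_map named character vector brand -> generic; brands absent
#'   from the map aggregate under their own name.
#' @return named list of 2x2 matrices, one per generic.
#' @export
aggregate_brands <- function(tables, generic_map = character()) {
  if (!length(tables)) stop("empty brand set")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be named by brand")
  }
  brands <- normalize_text(names(tables))
  gm <- stats::setNames(normalize_text(unname(generic_map)),
                        normalize_text(names(generic_map)))
  generic <- ifelse(brands %in% names(gm), gm[brands], brands)
  out <- lapply(split(seq_along(tables), generic), function(ix) {
    Reduce(`+`, tables[ix])
  })
  out[sort(names(out))]
}
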