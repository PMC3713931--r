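#' Classify the direction of a discordant ADR
#'
#' A discordant symptom sits at very different positions in the query-log
#' ranking and the report-database ranking (rank 1 = most prevalent). If its
#' reference rank is better (smaller) it is overemphasized in the reference
#' (typically an acute, readily reported reaction); if its QLRS rank is
#' better it is overemphasized in the query log (typically a late-onset,
#' under-reported one). Equal ranks are undetermined. The classification is
#' antisymmetric under swapping the two rankings.
#'
#' @param qlrs_rank,ref_rank numeric rank(s), 1 = most prevalent.
#' @return character vector: `"overemphasized_querylog"`,
#'   `"overemphasized_reference"` or `"undetermined"`.
#' @export
classify_discordance <- function(qlrs_rank, ref_rank) {
  ifelse(ref_rank < qlrs_rank, "overemphasized_reference",
         ifelse(qlrs_rank < ref_rank, "overemphasized_querylog",
                "undetermined"))
}

#' Greedy identification of the most discordant ADRs (MDADRs)
#'
#' Iteratively removes, `m` times, the symptom whose removal most increases
#' the Spearman rank correlation between the query-log scores and the
#' reference scores on the remaining set (equivalently, the symptom most
#' reducing the correlation by its presence). Ties break lexicographically.
#' The correlation trajectory is non-decreasing by construction. Each removed
#' symptom's direction records which source overemphasized it, from its
#' ranks in the full shared set.
#'
#' @param qlrs_scores named numeric: symptom -> QLRS.
#' @param ref_scores named numeric: symptom -> reference score (e.g. raw
#'   report counts).
#' @param m number of symptoms to remove (default 5; the design also uses
#'   larger values for particularly discordant drugs).
#' @param drug optional drug id carried into the result.
#' @return An object of class `mdadr`: list with `drug`, `rho_before`,
#'   `removed` (data.frame `symptom`, `rho_after`, `qlrs_rank`, `ref_rank`,
#'   `direction`), `m`, `remaining` (symptoms kept), `n0` (shared symptoms
#'   at the start).
#' @export
#' @examples
#' q <- c(s1 = 10, s2 = 8, s3 = 6, s4 = 4, s5 = 2)
#' r <- c(s1 = 100, s2 = 80, s3 = 5, s4 = 40, s5 = 20)
#' greedy_mdadr(q, r, m = 1)  # removes s3, rho 0.7 -> 1
greedy_mdadr <- function(qlrs_scores, ref_scores, m = 5, drug = NULL) {
  stopifnot(m >= 0)
  shared <- sort(intersect(names(qlrs_scores), names(ref_scores)))
  if (length(shared) < m + 3) {
    stop("need at least m + 3 shared symptoms (have ", length(shared), ")")
  }
  q <- as.numeric(qlrs_scores[shared]); names(q) <- shared
  r <- as.numeric(ref_scores[shared]); names(r) <- shared
  qrank <- rank(-q); rrank <- rank(-r)
  rho_before <- spearman_rho(q, r)$rho
  remaining <- shared
  rem <- data.frame(symptom = character(), rho_after = numeric(),
                    qlrs_rank = numeric(), ref_rank = numeric(),
                    direction = character())
  for (step in seq_len(m)) {
    best_rho <- -Inf
    best_sym <- NA_character_
    for (s in remaining) {        # remaining is sorted: first max wins ties
      rest <- remaining[remaining != s]
      rho_s <- suppressWarnings(spearman_rho(q[rest], r[rest])$rho)
      if (!is.na(rho_s) && rho_s > best_rho + 1e-12) {
        best_rho <- rho_s
        best_sym <- s
      }
    }
    if (is.na(best_sym)) break
    remaining <- remaining[remaining != best_sym]
    rem <- rbind(rem, data.frame(
      symptom = best_sym, rho_after = best_rho,
      qlrs_rank = qrank[[best_sym]], ref_rank = rrank[[best_sym]],
      direction = classify_discordance(qrank[[best_sym]], rrank[[best_sym]])))
  }
  rownames(rem) <- NULL
  structure(list(drug = drug, rho_before = rho_before, removed = rem,
                 m = nrow(rem), remaining = remaining, n0 = length(shared)),
            class = "mdadr")
}

#' @export
print.mdadr <- function(x, ...) {
  cat("Most discordant ADRs",
      if (!is.null(x$drug)) paste0(" for '", x$drug, "'"), "\n", sep = "")
  cat(sprintf("  rho before removal: %.3f (n = %d)\n", x$rho_before, x$n0))
  if (nrow(x$removed)) {
    cat(sprintf("  rho after removing %d: %.3f\n", x$m,
                x$removed$rho_after[x$m]))
    print(x$removed, digits = 3)
  } else {
    cat("  nothing removed\n")
  }
  invisible(x)
}

#' Temporal onset profile of a symptom after starting a drug
#'
#' Among exposed users, collects each user's first symptom query at or after
#' Day Zero (their first drug query) and summarises onsets as a cumulative
#' distribution over day offsets: `cdf[t]` is the fraction of exposed users
#' whose first post-Day-Zero symptom query occurred within `t` days. Only
#' first queries count, matching onset defined as the gap between the first
#' drug search and the first ADR search.
#'
#' @inheritParams build_contingency
#' @param horizon largest day offset tabulated (default 180).
#' @return An object of class `temporal_profile`: list with `drug`,
#'   `symptom`, `horizon`, `n_exposed`, `first_onset_days` (named per-user
#'   vector, NA when the user never queried the symptom after Day Zero) and
#'   `cdf` (numeric vector indexed 0..horizon).
#' @export
temporal_profile <- function(log, drug, symptom, dz = NULL, horizon = 180) {
  stopifnot(inherits(log, "query_log"), horizon >= 0)
  drug <- normalize_text(drug)
  symptom <- normalize_text(symptom)
  if (is.null(dz)) dz <- assign_day_zero(log, drug)
  dz <- dz[dz$exposed, , drop = FALSE]
  if (!nrow(dz)) stop("no exposed users for drug '", drug, "'")
  ev <- log$events
  ev <- ev[!is.na(ev$term) & ev$term == symptom & ev$user %in% dz$user, ,
           drop = FALSE]
  onset <- stats::setNames(rep(NA_real_, nrow(dz)), dz$user)
  if (nrow(ev)) {
    i <- match(ev$user, dz$user)
    off <- ev$day - dz$day_zero[i]
    ok <- off >= 0
    if (any(ok)) {
      first <- tapply(off[ok], ev$user[ok], min)
      onset[names(first)] <- as.numeric(first)
    }
  }
  cdf <- vapply(0:horizon, function(t) mean(!is.na(onset) & onset <= t),
                numeric(1))
  structure(list(drug = drug, symptom = symptom, horizon = horizon,
                 n_exposed = nrow(dz), first_onset_days = onset, cdf = cdf),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  obs <- x$first_onset_days[!is.na(x$first_onset_days)]
  cat("Temporal profile of '", x$symptom, "' after '", x$drug, "':\n",
      sep = "")
  cat(sprintf("  %d exposed users, %d with a post-Day-Zero query\n",
              x$n_exposed, length(obs)))
  if (length(obs)) {
    cat(sprintf("  mean onset %.1f days, median %.1f, cdf[%d] = %.3f\n",
                mean(obs), stats::median(obs), x$horizon,
                x$cdf[length(x$cdf)]))
  }
  invisible(x)
}

#' @export
plot.temporal_profile <- function(x, ...) {
  graphics::plot(0:x$horizon, x$cdf, type = "s",
                 xlab = "days since first drug query",
                 ylab = "P(first symptom query by day)",
                 main = paste0(x$symptom, " after ", x$drug), ...)
  invisible(x)
}

#' Paired test for the onset difference between MDADR classes
#'
#' Per drug, the mean first-onset delay of its query-log-overemphasized
#' MDADRs is paired with that of its reference-overemphasized MDADRs; the
#' across-drug differences are tested with a two-sided Wilcoxon signed-rank
#' test. A positive mean difference says the query-log-emphasized reactions
#' surface later after treatment start — the signature of late-onset ADRs
#' that elude spontaneous reporting.
#'
#' @param onset_querylog,onset_reference numeric vectors of per-drug mean
#'   onsets (days), paired by position; pairs with missing values are
#'   dropped.
#' @return list with `mean_difference` (days), `p.value`, `n` (pairs used).
#' @export
onset_difference_test <- function(onset_querylog, onset_reference) {
  if (length(onset_querylog) != length(onset_reference)) {
    stop("onset vectors must be paired (same length)")
  }
  d <- onset_querylog - onset_reference
  d <- d[!is.na(d)]
  if (length(d) < 5) stop("need at least 5 paired per-drug onsets, have ",
                          length(d))
  if (all(d == 0)) {
    return(list(mean_difference = 0, p.value = 1, n = length(d)))
  }
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0,
                                            alternative = "two.sided"))
  list(mean_difference = mean(d), p.value = wt$p.value, n = length(d))
}

#' Evaluate a ranking against a binary known-ADR reference
#'
#' AUC is the probability that a known ADR outranks a non-listed symptom
#' (rank-sum estimator, ties counted one half). The F score binarises the
#' ranking at a QLRS threshold, by default the chi-square(1) p < .05 cutoff
#' 3.841, and is the harmonic mean of precision and recall.
#'
#' @param scores named numeric: symptom -> score (higher = more ADR-like).
#' @param labels a [label_set()], or a character vector of positive symptom
#'   ids.
#' @param drug drug id used to filter `labels` when it is a label set.
#' @param threshold score cutoff for the F score.
#' @return list with `auc`, `f_score`, `precision`, `recall`, `threshold`,
#'   `n_pos`, `n_neg`.
#' @export
evaluate_against_positives <- function(scores, labels, drug = NULL,
                                       threshold = stats::qchisq(0.95, 1)) {
  if (inherits(labels, "label_set")) {
    if (is.null(drug)) stop("drug needed to filter a label set")
    pos_ids <- labels$symptom[labels$drug == normalize_text(drug)]
  } else {
    pos_ids <- normalize_text(labels)
  }
  if (is.null(names(scores))) stop("scores must be named by symptom")
  y <- names(scores) %in% pos_ids
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative among scored symptoms")
  }
  r <- rank(scores)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  pred <- scores >= threshold
  tp <- sum(pred & y)
  precision <- if (sum(pred)) tp / sum(pred) else NA_real_
  recall <- tp / n_pos
  f <- if (!is.na(precision) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else if (is.na(precision)) NA_real_ else 0
  list(auc = auc, f_score = f, precision = precision, recall = recall,
       threshold = threshold, n_pos = n_pos, n_neg = n_neg)
}
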