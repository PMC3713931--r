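#' Partition users for a drug-pair analysis
#'
#' Three disjoint populations: users who searched for only drug i, only drug
#' j, and both. Day Zero for the single-drug groups is the first search for
#' their drug; for the both-drugs group it is the later of the two first
#' searches (the commencement of the combination). Disjointness is defined
#' with respect to the pair only — exposure to unrelated drugs does not
#' exclude a user.
#'
#' @param log a [query_log()].
#' @param drug_i,drug_j canonical drug ids.
#' @return An object of class `pair_populations`: list with `drug_i`,
#'   `drug_j`, `users_i_only`, `users_j_only`, `users_both` (character
#'   vectors) and `day_zero` (named integer vector over users in any group).
#' @export
partition_pair_populations <- function(log, drug_i, drug_j) {
  stopifnot(inherits(log, "query_log"))
  drug_i <- normalize_text(drug_i)
  drug_j <- normalize_text(drug_j)
  if (drug_i == drug_j) stop("drug_i and drug_j must differ")
  dzi <- assign_day_zero(log, drug_i)
  dzj <- assign_day_zero(log, drug_j)
  stopifnot(identical(dzi$user, dzj$user))
  ei <- dzi$exposed; ej <- dzj$exposed
  users_i <- dzi$user[ei & !ej]
  users_j <- dzi$user[ej & !ei]
  users_b <- dzi$user[ei & ej]
  dz <- integer(0)
  dz <- c(stats::setNames(dzi$day_zero[match(users_i, dzi$user)], users_i),
          stats::setNames(dzj$day_zero[match(users_j, dzj$user)], users_j),
          stats::setNames(pmax(dzi$day_zero[match(users_b, dzi$user)],
                               dzj$day_zero[match(users_b, dzj$user)]),
                          users_b))
  if (!length(users_i) || !length(users_j) || !length(users_b)) {
    warning("empty pair population(s): ",
            paste(c("i_only", "j_only", "both")[
              !c(length(users_i), length(users_j), length(users_b))],
              collapse = ", "))
  }
  structure(list(drug_i = drug_i, drug_j = drug_j,
                 users_i_only = users_i, users_j_only = users_j,
                 users_both = users_b, day_zero = dz),
            class = "pair_populations")
}

#' Prevalence-change ratio
#'
#' The fraction of a symptom's queries falling after Day Zero,
#' `n_after / (n_before + n_after)`; missing (NA) when the symptom was never
#' queried in that population.
#'
#' @param n_before,n_after non-negative counts (vectorised).
#' @return numeric vector in `[0, 1]`, NA where both counts are zero.
#' @export
change_ratio <- function(n_before, n_after) {
  stopifnot(all(n_before >= 0), all(n_after >= 0))
  tot <- n_before + n_after
  ifelse(tot > 0, n_after / tot, NA_real_)
}

#' Per-symptom change ratios for the three pair populations
#'
#' @inheritParams partition_pair_populations
#' @param symptoms symptom universe to tabulate.
#' @param pp optional precomputed [partition_pair_populations()].
#' @param boundary Day-Zero side convention, as in [build_contingency()].
#' @return data.frame with one row per symptom: before/after counts and
#'   ratios `r_i`, `r_j`, `r_both` for each population.
#' @export
pair_ratios <- function(log, drug_i, drug_j, symptoms, pp = NULL,
                        boundary = c("after", "before")) {
  stopifnot(inherits(log, "query_log"))
  boundary <- match.arg(boundary)
  symptoms <- normalize_text(symptoms)
  if (is.null(pp)) pp <- partition_pair_populations(log, drug_i, drug_j)
  ev <- log$events
  ev <- ev[!is.na(ev$term) & ev$term %in% symptoms, , drop = FALSE]
  count_pop <- function(users) {
    sub <- ev[ev$user %in% users, , drop = FALSE]
    if (nrow(sub)) {
      dz <- pp$day_zero[sub$user]
      aft <- if (boundary == "after") sub$day >= dz else sub$day > dz
      f <- factor(sub$term, levels = symptoms)
      nb <- as.integer(tapply(!aft, f, sum, default = 0L))
      na_ <- as.integer(tapply(aft, f, sum, default = 0L))
    } else {
      nb <- na_ <- integer(length(symptoms))
    }
    list(nb = nb, na = na_)
  }
  ci <- count_pop(pp$users_i_only)
  cj <- count_pop(pp$users_j_only)
  cb <- count_pop(pp$users_both)
  data.frame(symptom = symptoms,
             nb_i = ci$nb, na_i = ci$na, r_i = change_ratio(ci$nb, ci$na),
             nb_j = cj$nb, na_j = cj$na, r_j = change_ratio(cj$nb, cj$na),
             nb_both = cb$nb, na_both = cb$na,
             r_both = change_ratio(cb$nb, cb$na))
}

#' Fit the single-drug discounting regression for a drug pair
#'
#' Ordinary least squares of the both-drugs change ratio on the two
#' single-drug change ratios, `r_both ~ c + b_i r_i + b_j r_j`, over symptoms
#' with all three ratios defined. The fit discounts the ADRs each drug causes
#' on its own; a symptom whose observed `r_both` sits far above the linear
#' prediction is a candidate interaction ADR. Standardized residuals divide
#' by the (leave-in) residual standard error.
#'
#' @param ratios data.frame from [pair_ratios()] (columns `symptom`, `r_i`,
#'   `r_j`, `r_both`).
#' @return An object of class `pair_fit`: list with `coefficients`, `sigma`,
#'   `table` (per-symptom observed/fitted/residual/std_residual), `excluded`
#'   (symptoms with missing ratios), `n`, `model` (the underlying `lm`) and
#'   `pair`.
#' @export
fit_pair_model <- function(ratios) {
  need <- c("symptom", "r_i", "r_j", "r_both")
  if (!all(need %in% names(ratios))) {
    stop("ratios need columns ", paste(need, collapse = ", "))
  }
  cc <- stats::complete.cases(ratios[, c("r_i", "r_j", "r_both")])
  excluded <- as.character(ratios$symptom[!cc])
  d <- ratios[cc, , drop = FALSE]
  if (nrow(d) < 5) {
    stop("need at least 5 symptoms with all three ratios defined, have ",
         nrow(d))
  }
  fit <- stats::lm(r_both ~ r_i + r_j, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: r_i and r_j are collinear ",
         "(singular values: ",
         paste(format(svd(cbind(1, d$r_i, d$r_j))$d, digits = 3),
               collapse = ", "), ")")
  }
  res <- stats::resid(fit)
  sigma <- sqrt(sum(res^2) / (nrow(d) - 3))
  std <- if (sigma > 0) res / sigma else rep(0, length(res))
  tab <- data.frame(symptom = as.character(d$symptom),
                    r_i = d$r_i, r_j = d$r_j, r_both = d$r_both,
                    fitted = as.numeric(stats::fitted(fit)),
                    residual = as.numeric(res),
                    std_residual = as.numeric(std))
  rownames(tab) <- NULL
  structure(list(coefficients = stats::coef(fit), sigma = sigma,
                 table = tab, excluded = excluded, n = nrow(d),
                 model = fit,
                 pair = attr(ratios, "pair")),
            class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat("Drug-pair interaction fit")
  if (!is.null(x$pair)) cat(" (", paste(x$pair, collapse = " + "), ")", sep = "")
  cat("\n  r_both ~ ", sprintf("%.3f + %.3f r_i + %.3f r_j",
                               x$coefficients[1], x$coefficients[2],
                               x$coefficients[3]),
      "   [n = ", x$n, ", sigma = ", sprintf("%.3f", x$sigma), "]\n",
      sep = "")
  if (length(x$excluded)) {
    cat("  excluded (missing ratios): ", paste(x$excluded, collapse = ", "),
        "\n", sep = "")
  }
  top <- utils::head(interaction_ranking(x, positive_only = TRUE), 5)
  if (nrow(top)) {
    cat("  top candidate interaction ADRs:\n")
    print(top[, c("symptom", "r_both", "fitted", "std_residual")], digits = 3)
  }
  invisible(x)
}

#' @export
residuals.pair_fit <- function(object, standardized = FALSE, ...) {
  stats::setNames(
    if (standardized) object$table$std_residual else object$table$residual,
    object$table$symptom)
}

#' @export
coef.pair_fit <- function(object, ...) object$coefficients

#' @export
predict.pair_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::setNames(object$table$fitted,
                                               object$table$symptom))
  as.numeric(stats::predict(object$model, newdata = newdata))
}

#' Rank candidate interaction ADRs
#'
#' Symptoms sorted by decreasing standardized residual of the pair fit; with
#' `positive_only` (default) only symptoms whose combined-population change
#' ratio exceeds the prediction are kept, since interaction ADR discovery
#' looks for increases.
#'
#' @param result a [fit_pair_model()] object.
#' @param positive_only keep only positive residuals.
#' @return data.frame sorted by `std_residual` descending.
#' @export
interaction_ranking <- function(result, positive_only = TRUE) {
  stopifnot(inherits(result, "pair_fit"))
  tab <- result$table
  # strictly positive beyond numerical noise of the least-squares solve
  if (positive_only) tab <- tab[tab$residual > 1e-10, , drop = FALSE]
  tab <- tab[order(-tab$std_residual, tab$symptom), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' End-to-end drug-pair interaction analysis
#'
#' Convenience wrapper: partitions the pair populations, tabulates change
#' ratios over the symptom universe and fits the discounting regression.
#'
#' @inheritParams pair_ratios
#' @param dictionary optional [term_dictionary()] supplying the symptom
#'   universe when `symptoms` is NULL.
#' @return A `pair_fit` (see [fit_pair_model()]).
#' @export
drug_interaction <- function(log, drug_i, drug_j, dictionary = NULL,
                             symptoms = NULL,
                             boundary = c("after", "before")) {
  boundary <- match.arg(boundary)
  if (is.null(symptoms)) {
    if (!is.null(dictionary)) {
      symptoms <- dictionary$symptoms
    } else {
      symptoms <- setdiff(unique(log$events$term[!is.na(log$events$term)]),
                          normalize_text(c(drug_i, drug_j)))
    }
  }
  pp <- partition_pair_populations(log, drug_i, drug_j)
  ratios <- pair_ratios(log, drug_i, drug_j, symptoms, pp = pp,
                        boundary = boundary)
  attr(ratios, "pair") <- c(pp$drug_i, pp$drug_j)
  fit_pair_model(ratios)
}
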