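#' Expected report counts under row/column independence
#'
#' For a report database, the expected count of a (drug, symptom) cell under
#' independence is `drug_margin * symptom_margin / grand_total` — the
#' baseline every disproportionality statistic shrinks or scales against.
#'
#' @param rc a [report_counts()] object.
#' @return matrix of expected counts, same shape as `rc$counts`.
#' @export
expected_counts <- function(rc) {
  stopifnot(inherits(rc, "report_counts"))
  if (rc$grand_total <= 0) stop("empty report table")
  outer(rc$drug_margins, rc$symptom_margins) / rc$grand_total
}

#' @rdname expected_counts
#' @param drug,symptom ids; a pair absent from the database has expected
#'   count 0.
#' @return `expected_count()`: a single number.
#' @export
expected_count <- function(rc, drug, symptom) {
  stopifnot(inherits(rc, "report_counts"))
  if (rc$grand_total <= 0) stop("empty report table")
  drug <- normalize_text(drug)
  symptom <- normalize_text(symptom)
  dm <- if (drug %in% rc$drugs) rc$drug_margins[[drug]] else 0
  sm <- if (symptom %in% rc$symptoms) rc$symptom_margins[[symptom]] else 0
  dm * sm / rc$grand_total
}

#' Information component (IC)
#'
#' Shrunken log2 observed/expected report ratio from the Bayesian confidence
#' propagation tradition: `log2((n + 0.5) / (E + 0.5))`. The half counts pull
#' small cells toward 0; the statistic is strictly increasing in `n` and
#' strictly decreasing in `E`.
#'
#' @param n_obs observed report count(s).
#' @param e_exp expected count(s) under independence.
#' @return numeric vector.
#' @export
#' @examples
#' ic_score(20, 2)  # log2(8.2)
ic_score <- function(n_obs, e_exp) {
  stopifnot(all(n_obs >= 0), all(e_exp >= 0))
  log2((n_obs + 0.5) / (e_exp + 0.5))
}

#' Two-gamma mixture prior for the empirical Bayes geometric mean
#'
#' Container for the hyperparameters of DuMouchel's gamma-Poisson shrinker:
#' the report-rate ratio lambda is a priori
#' `w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2)`
#' (shape/rate), and a cell's count is Poisson with mean `E * lambda`.
#'
#' @param alpha1,beta1,alpha2,beta2 positive gamma shape/rate parameters.
#' @param w mixture weight in (0, 1).
#' @param loglik,convergence,n_cells fit metadata (set by [fit_ebgm()]).
#' @return An object of class `ebgm_prior`.
#' @export
ebgm_prior <- function(alpha1, beta1, alpha2, beta2, w,
                       loglik = NA_real_, convergence = NA_integer_,
                       n_cells = NA_integer_) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w > 0, w < 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w, loglik = loglik,
                 convergence = convergence, n_cells = n_cells),
            class = "ebgm_prior")
}

#' @export
print.ebgm_prior <- function(x, ...) {
  cat("EBGM two-gamma mixture prior\n")
  cat(sprintf("  component 1: Gamma(shape = %.4g, rate = %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(shape = %.4g, rate = %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  cat(sprintf("  prior mean lambda: %.4g\n",
              x$w * x$alpha1 / x$beta1 + (1 - x$w) * x$alpha2 / x$beta2))
  if (!is.na(x$loglik)) {
    cat(sprintf("  marginal log-likelihood: %.2f over %d cells\n",
                x$loglik, x$n_cells))
  }
  invisible(x)
}

#' Density of the mixture prior
#'
#' @param x an [ebgm_prior()].
#' @param lambda evaluation points.
#' @return numeric vector of densities.
#' @export
ebgm_prior_density <- function(x, lambda) {
  stopifnot(inherits(x, "ebgm_prior"))
  x$w * stats::dgamma(lambda, x$alpha1, rate = x$beta1) +
    (1 - x$w) * stats::dgamma(lambda, x$alpha2, rate = x$beta2)
}

# negative marginal log-likelihood on transformed parameters
.ebgm_nll <- function(theta, n, e) {
  a1 <- exp(theta[1]); b1 <- exp(theta[2])
  a2 <- exp(theta[3]); b2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  l1 <- stats::dnbinom(n, size = a1, prob = b1 / (b1 + e), log = TRUE) + log(w)
  l2 <- stats::dnbinom(n, size = a2, prob = b2 / (b2 + e), log = TRUE) +
    log1p(-w)
  m <- pmax(l1, l2)
  val <- -sum(m + log(exp(l1 - m) + exp(l2 - m)))
  if (!is.finite(val)) val <- .Machine$double.xmax / 1e6
  val
}

#' Fit the EBGM mixture prior by marginal maximum likelihood
#'
#' Marginalising the Poisson over the gamma mixture makes each cell count a
#' two-component negative binomial mixture; the five hyperparameters are
#' estimated by maximising that marginal likelihood over all cells with
#' positive expected count (Nelder-Mead then BFGS polish), started from
#' DuMouchel's published starting point (alpha1 = 0.2, beta1 = 0.1,
#' alpha2 = 2, beta2 = 4, w = 1/3). On non-convergence an error of class
#' `ebgm_convergence_error` is signalled carrying the best iterate in its
#' `best` field; callers may fall back to the starting-point prior.
#'
#' @param rc a [report_counts()] object (expected counts derived from its
#'   margins), or a list with elements `n` and `e` giving observed/expected
#'   pairs directly.
#' @param start named numeric starting values
#'   (`alpha1`, `beta1`, `alpha2`, `beta2`, `w`).
#' @param maxit Nelder-Mead iteration cap.
#' @return An [ebgm_prior()] with `loglik`, `convergence` and `n_cells` set.
#' @export
fit_ebgm <- function(rc,
                     start = c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2,
                               beta2 = 4, w = 1 / 3),
                     maxit = 2000) {
  if (inherits(rc, "report_counts")) {
    e <- as.vector(expected_counts(rc))
    n <- as.vector(rc$counts)
  } else if (is.list(rc) && !is.null(rc$n) && !is.null(rc$e)) {
    # (n, E) pairs supplied directly, as DuMouchel's software consumes them
    n <- as.numeric(rc$n)
    e <- as.numeric(rc$e)
    stopifnot(length(n) == length(e))
  } else {
    stop("rc must be a report_counts object or a list with n and e")
  }
  keep <- e > 0
  n <- n[keep]; e <- e[keep]
  if (!length(n)) stop("empty report table")
  if (sum(n > 0) < 50) {
    warning("only ", sum(n > 0),
            " nonempty cells; EBGM prior estimates will be unstable")
  }
  th0 <- c(log(start[["alpha1"]]), log(start[["beta1"]]),
           log(start[["alpha2"]]), log(start[["beta2"]]),
           stats::qlogis(start[["w"]]))
  o <- stats::optim(th0, .ebgm_nll, n = n, e = e, method = "Nelder-Mead",
                    control = list(maxit = maxit))
  o2 <- tryCatch(
    stats::optim(o$par, .ebgm_nll, n = n, e = e, method = "BFGS",
                 control = list(maxit = 200)),
    error = function(err) NULL)
  if (!is.null(o2) && o2$value <= o$value) o <- o2
  th <- o$par
  prior <- ebgm_prior(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                      alpha2 = exp(th[3]), beta2 = exp(th[4]),
                      w = stats::plogis(th[5]),
                      loglik = -o$value, convergence = o$convergence,
                      n_cells = length(n))
  if (o$convergence != 0) {
    stop(errorCondition(
      paste0("EBGM prior fit did not converge (optim code ", o$convergence,
             "); best iterate attached as $best"),
      class = "ebgm_convergence_error", best = prior))
  }
  prior
}

#' Empirical Bayes geometric mean (EBGM) score
#'
#' Given the mixture prior, the posterior of the rate ratio lambda for a cell
#' with `n_obs` reports and expected count `e_exp` is again a two-gamma
#' mixture with components `Gamma(alpha_j + n, beta_j + E)` and weights
#' proportional to the prior weight times the component's negative-binomial
#' marginal. EBGM is the geometric mean of that posterior,
#' `exp(E[log lambda])`, computed with the digamma function per component.
#' Shrinkage vanishes for large counts: EBGM approaches `n/E`.
#'
#' @inheritParams ic_score
#' @param prior an [ebgm_prior()].
#' @return numeric vector of EBGM scores.
#' @export
ebgm_score <- function(n_obs, e_exp, prior) {
  stopifnot(inherits(prior, "ebgm_prior"))
  if (any(e_exp <= 0)) stop("ebgm_score undefined for e_exp = 0")
  k <- max(length(n_obs), length(e_exp))
  n <- rep_len(n_obs, k); e <- rep_len(e_exp, k)
  l1 <- stats::dnbinom(n, size = prior$alpha1,
                       prob = prior$beta1 / (prior$beta1 + e), log = TRUE) +
    log(prior$w)
  l2 <- stats::dnbinom(n, size = prior$alpha2,
                       prob = prior$beta2 / (prior$beta2 + e), log = TRUE) +
    log1p(-prior$w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  eln <- q1 * (digamma(prior$alpha1 + n) - log(prior$beta1 + e)) +
    (1 - q1) * (digamma(prior$alpha2 + n) - log(prior$beta2 + e))
  exp(eln)
}

#' Spearman rank correlation between two score maps
#'
#' Average-rank tie handling; the two-sided p value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Named vectors are aligned on their shared names.
#'
#' @param scores_a,scores_b numeric vectors; if named, the intersection of
#'   names is used, otherwise they are paired positionally.
#' @return list with `rho`, `p.value`, `n`.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
spearman_rho <- function(scores_a, scores_b) {
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    shared <- intersect(names(scores_a), names(scores_b))
    a <- as.numeric(scores_a[shared])
    b <- as.numeric(scores_b[shared])
  } else {
    if (length(scores_a) != length(scores_b)) {
      stop("unnamed score vectors must have equal length")
    }
    a <- as.numeric(scores_a)
    b <- as.numeric(scores_b)
  }
  n <- length(a)
  if (n < 3) stop("need at least 3 shared symptoms, got ", n)
  ra <- rank(a); rb <- rank(b)
  da <- ra - mean(ra); db <- rb - mean(rb)
  va <- sum(da^2); vb <- sum(db^2)
  if (va == 0 || vb == 0) {
    warning("constant ranks; rho undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = n))
  }
  rho <- sum(da * db) / sqrt(va * vb)
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Combine per-drug rank correlations by meta-analysis
#'
#' Fixed-effect pooling on the Fisher-z scale with weights `n - 3`,
#' back-transformed; the two-sided p value comes from the pooled z. Studies
#' with fewer than 4 shared symptoms are excluded with a warning. A
#' DerSimonian-Laird random-effects variant is available via `method`.
#'
#' @param results data.frame with columns `rho` and `n` (one row per drug),
#'   or a list of `list(rho =, n =)` entries.
#' @param method `"fixed"` (default) or `"DL"`.
#' @return list with `rho` (combined estimate), `p.value`, `z`, `se`, `k`
#'   (studies used), `tau2` (0 under fixed effects), `method`.
#' @export
meta_combine <- function(results, method = c("fixed", "DL")) {
  method <- match.arg(method)
  if (is.data.frame(results)) {
    rho <- results$rho; n <- results$n
  } else {
    rho <- vapply(results, function(r) r$rho, numeric(1))
    n <- vapply(results, function(r) r$n, numeric(1))
  }
  ok <- !is.na(rho) & n >= 4
  if (any(!ok)) {
    warning(sum(!ok), " study(ies) excluded (n < 4 or missing rho)")
  }
  rho <- rho[ok]; n <- n[ok]
  if (!length(rho)) stop("no usable studies")
  rho <- pmin(pmax(rho, -0.999999), 0.999999)
  z <- atanh(rho)
  w <- n - 3
  zbar <- sum(w * z) / sum(w)
  tau2 <- 0
  if (method == "DL" && length(z) > 1) {
    q <- sum(w * (z - zbar)^2)
    tau2 <- max(0, (q - (length(z) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (1 / w + tau2)
    zbar <- sum(w * z) / sum(w)
  }
  se <- sqrt(1 / sum(w))
  p <- 2 * stats::pnorm(-abs(zbar / se))
  list(rho = tanh(zbar), p.value = p, z = zbar, se = se,
       k = length(z), tau2 = tau2, method = method)
}

#' Compare a QLRS ranking with a report database
#'
#' Computes the Spearman correlations between the QLRS ranking of a drug's
#' symptoms and three reference rankings from the report database: raw report
#' counts (rho1), EBGM (rho2) and IC (rho3), all evaluated on the same shared
#' symptom subset (the drug's scored symptoms intersected with the database,
#' after any MDADR removal the caller applies).
#'
#' @param fit a [qlrs()] fit, or a named numeric vector of QLRS scores.
#' @param rc a [report_counts()] object.
#' @param prior an [ebgm_prior()]; fitted from `rc` via [fit_ebgm()] when
#'   NULL (with fallback to the DuMouchel starting-point prior if the fit
#'   does not converge).
#' @param drug drug id (taken from the fit when omitted).
#' @return one-row data.frame: `drug`, `n`, `rho1`, `p1`, `rho2`, `p2`,
#'   `rho3`, `p3`.
#' @export
compare_rankings <- function(fit, rc, prior = NULL, drug = NULL) {
  stopifnot(inherits(rc, "report_counts"))
  if (inherits(fit, "qlrs")) {
    drug <- drug %||% fit$drug
    q <- stats::setNames(fit$scores$qlrs, fit$scores$symptom)
  } else {
    if (is.null(drug)) stop("drug must be given with a raw score vector")
    q <- fit
  }
  drug <- normalize_text(drug)
  if (!drug %in% rc$drugs) stop("drug '", drug, "' not in report database")
  shared <- intersect(names(q), rc$symptoms)
  if (length(shared) < 3) stop("fewer than 3 shared symptoms")
  nobs <- rc$counts[drug, shared]
  eexp <- expected_counts(rc)[drug, shared]
  if (is.null(prior)) {
    prior <- tryCatch(fit_ebgm(rc), ebgm_convergence_error = function(err) {
      warning("EBGM prior fit did not converge; using best iterate")
      err$best %||% ebgm_prior(0.2, 0.1, 2, 4, 1 / 3)
    })
  }
  pos <- eexp > 0
  r1 <- spearman_rho(q[shared], nobs)
  r2 <- spearman_rho(q[shared][pos], ebgm_score(nobs[pos], eexp[pos], prior))
  r3 <- spearman_rho(q[shared], ic_score(nobs, eexp))
  data.frame(drug = drug, n = r1$n,
             rho1 = r1$rho, p1 = r1$p.value,
             rho2 = r2$rho, p2 = r2$p.value,
             rho3 = r3$rho, p3 = r3$p.value)
}
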