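#' Reporting model for the synthetic spontaneous-report database
#'
#' Expected planted report counts are
#' `n_exposed * (multiplier - 1) * per_exposed * acuteness *
#' exp(-mean_onset_delay / decay_days)`: reporting falls off with onset delay
#' because patients and clinicians link a reaction to a drug far more easily
#' when it appears shortly after commencing treatment, and acute reactions
#' carry an extra weight. Null cells receive Poisson background noise.
#'
#' @param per_exposed expected reports per exposed user per unit effect size
#'   at zero delay (default 0.02).
#' @param decay_days exponential decay scale of reporting probability with
#'   mean onset delay (default 30 days).
#' @param background mean background report count per (drug, symptom) cell
#'   (default 2).
#' @return list of class `sim_reporting`.
#' @export
sim_reporting <- function(per_exposed = 0.02, decay_days = 30,
                          background = 2) {
  stopifnot(per_exposed >= 0, decay_days > 0, background >= 0)
  structure(list(per_exposed = per_exposed, decay_days = decay_days,
                 background = background), class = "sim_reporting")
}

#' Declare a planted ADR effect
#'
#' After a sampled onset delay following Day Zero, the affected symptom's
#' query rate among exposed users is multiplied by `multiplier` for
#' `duration` days. Two onset presets cover the two reaction classes the
#' discordance analysis contrasts: `"geometric"` (acute, delay ~
#' Geometric(prob), mean `(1-p)/p` days) and `"uniform"` (late onset, delay
#' uniform on `[onset_par1, onset_par2]` days).
#'
#' @param drug,symptom canonical ids.
#' @param multiplier rate multiplier >= 1.
#' @param onset `"geometric"` or `"uniform"`.
#' @param onset_par1 geometric success probability, or uniform lower bound.
#' @param onset_par2 uniform upper bound (ignored for geometric).
#' @param duration effect duration in days (default `Inf`).
#' @param acuteness reporting weight multiplier (default 1); high values
#'   emulate dramatic reactions that are reported far beyond their query
#'   footprint.
#' @return one-row data.frame; `rbind()` several to build an effect table.
#' @export
adr_effect <- function(drug, symptom, multiplier,
                       onset = c("geometric", "uniform"),
                       onset_par1 = 0.4, onset_par2 = NA_real_,
                       duration = Inf, acuteness = 1) {
  onset <- match.arg(onset)
  stopifnot(multiplier >= 1, acuteness >= 0, duration >= 1)
  if (onset == "geometric") {
    stopifnot(onset_par1 > 0, onset_par1 <= 1)
  } else {
    stopifnot(!is.na(onset_par2), onset_par1 >= 0, onset_par2 >= onset_par1)
  }
  data.frame(drug = normalize_text(drug), symptom = normalize_text(symptom),
             multiplier = multiplier, onset = onset,
             onset_par1 = onset_par1, onset_par2 = onset_par2,
             duration = duration, acuteness = acuteness)
}

.mean_delay <- function(eff) {
  ifelse(eff$onset == "geometric", (1 - eff$onset_par1) / eff$onset_par1,
         (eff$onset_par1 + eff$onset_par2) / 2)
}

#' Configuration of the synthetic query-log world
#'
#' The simulator emulates the observational regime the method targets: each
#' user is active over a window of days inside a 6-month log span; drugs are
#' adopted independently with per-drug probability and first searched on a
#' uniform day of the user's window; symptom queries arrive as per-day
#' Poisson counts with a per-symptom baseline rate modulated by a shared
#' seasonal sinusoid; planted ADR effects multiply an exposed user's rate
#' after Day Zero plus a sampled onset delay. Identical configurations
#' (including the seed) reproduce the log bit for bit.
#'
#' @param n_users number of users.
#' @param span_days log span in days (default 180, a 6-month log).
#' @param drugs named numeric vector: drug id -> adoption probability.
#' @param symptoms named numeric vector: symptom id -> baseline query rate
#'   per user-day. The package default elsewhere is 0.001 (about 0.18
#'   queries per symptom per user per 6 months) — the sparse regime real
#'   health queries live in, and the regime in which the chi-square null is
#'   calibrated (see the methods vignette).
#' @param seasonal_amplitude amplitude of the shared seasonal sinusoid in
#'   `[0, 1)` (default 0.2).
#' @param seasonal_period period of the sinusoid in days (default 365).
#' @param effects data.frame of planted single-drug effects
#'   (see [adr_effect()]).
#' @param pair_effects data.frame of planted interaction effects with
#'   columns `drug_i`, `drug_j`, plus the [adr_effect()] columns; the
#'   multiplier applies to users exposed to both drugs from
#'   `max(day_zero_i, day_zero_j)` plus the onset delay.
#' @param reporting a [sim_reporting()].
#' @param min_window minimum user activity window length in days
#'   (default 60).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_users, span_days = 180, drugs, symptoms,
                       seasonal_amplitude = 0.2, seasonal_period = 365,
                       effects = NULL, pair_effects = NULL,
                       reporting = sim_reporting(), min_window = 60,
                       seed = 1) {
  if (!is.numeric(n_users) || length(n_users) != 1 || n_users < 0) {
    stop("invalid config field `n_users`: must be a single count >= 0")
  }
  if (span_days < 1) stop("invalid config field `span_days`: must be >= 1")
  if (is.null(names(drugs)) || any(!nzchar(names(drugs)))) {
    stop("invalid config field `drugs`: must be a named vector of adoption probabilities")
  }
  if (any(drugs < 0 | drugs > 1)) {
    stop("invalid config field `drugs`: probabilities must lie in [0, 1]")
  }
  if (is.null(names(symptoms)) || any(!nzchar(names(symptoms)))) {
    stop("invalid config field `symptoms`: must be a named vector of rates")
  }
  if (any(symptoms < 0)) {
    stop("invalid config field `symptoms`: rates must be >= 0")
  }
  if (seasonal_amplitude < 0 || seasonal_amplitude >= 1) {
    stop("invalid config field `seasonal_amplitude`: must lie in [0, 1)")
  }
  if (min_window < 1 || min_window > span_days) {
    stop("invalid config field `min_window`: must lie in [1, span_days]")
  }
  names(drugs) <- normalize_text(names(drugs))
  names(symptoms) <- normalize_text(names(symptoms))
  check_eff <- function(eff, cols, what) {
    if (is.null(eff) || !nrow(eff)) return(NULL)
    if (!all(cols %in% names(eff))) {
      stop("invalid config field `", what, "`: needs columns ",
           paste(cols, collapse = ", "))
    }
    if (is.null(eff$acuteness)) eff$acuteness <- 1
    if (is.null(eff$duration)) eff$duration <- Inf
    if (any(eff$multiplier < 1)) {
      stop("invalid config field `", what, "`: multipliers must be >= 1")
    }
    bad <- !normalize_text(eff$symptom) %in% names(symptoms)
    if (any(bad)) {
      stop("invalid config field `", what, "`: unknown symptom(s) ",
           paste(unique(eff$symptom[bad]), collapse = ", "))
    }
    eff$symptom <- normalize_text(eff$symptom)
    eff
  }
  effects <- check_eff(effects,
                       c("drug", "symptom", "multiplier", "onset",
                         "onset_par1"), "effects")
  if (!is.null(effects)) {
    effects$drug <- normalize_text(effects$drug)
    if (any(!effects$drug %in% names(drugs))) {
      stop("invalid config field `effects`: unknown drug(s)")
    }
  }
  pair_effects <- check_eff(pair_effects,
                            c("drug_i", "drug_j", "symptom", "multiplier",
                              "onset", "onset_par1"), "pair_effects")
  if (!is.null(pair_effects)) {
    pair_effects$drug_i <- normalize_text(pair_effects$drug_i)
    pair_effects$drug_j <- normalize_text(pair_effects$drug_j)
    if (any(!c(pair_effects$drug_i, pair_effects$drug_j) %in% names(drugs))) {
      stop("invalid config field `pair_effects`: unknown drug(s)")
    }
  }
  stopifnot(inherits(reporting, "sim_reporting"))
  structure(list(n_users = as.integer(n_users),
                 span_days = as.integer(span_days),
                 drugs = drugs, symptoms = symptoms,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_period = seasonal_period,
                 effects = effects, pair_effects = pair_effects,
                 reporting = reporting,
                 min_window = as.integer(min_window),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.empty_log <- function() {
  query_log(data.frame(user = character(), day = integer(),
                       term = character(), event = integer()))
}

#' Simulate a query log with planted ADR structure
#'
#' See [sim_config()] for the generative model. Returns both the log and the
#' ground truth needed for recovery tests: the planted effect tables with
#' their mean onset delays, per-drug exposure (user -> first-search day) and
#' realised exposure counts.
#'
#' @param cfg a [sim_config()].
#' @return list with `log` (a [query_log()]) and `truth` (class
#'   `sim_ground_truth`: list with `effects`, `pair_effects`, `exposure`,
#'   `n_exposed`, `seed`).
#' @export
simulate_query_log <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .simulate_ql(cfg))
}

.simulate_ql <- function(cfg) {
  u_n <- cfg$n_users
  span <- cfg$span_days
  truth_base <- function(exposure, n_exposed) {
    eff <- cfg$effects
    if (!is.null(eff)) eff$mean_delay <- .mean_delay(eff)
    peff <- cfg$pair_effects
    if (!is.null(peff)) peff$mean_delay <- .mean_delay(peff)
    structure(list(effects = eff, pair_effects = peff,
                   exposure = exposure, n_exposed = n_exposed,
                   drugs = names(cfg$drugs), symptoms = names(cfg$symptoms),
                   seed = cfg$seed),
              class = "sim_ground_truth")
  }
  if (u_n == 0) {
    return(list(log = .empty_log(),
                truth = truth_base(list(),
                                   stats::setNames(integer(length(cfg$drugs)),
                                                   names(cfg$drugs)))))
  }
  users <- sprintf("u%06d", seq_len(u_n))
  # activity windows
  start <- sample.int(span - cfg$min_window + 1L, u_n, replace = TRUE) - 1L
  maxlen <- span - start
  len <- cfg$min_window +
    floor(stats::runif(u_n) * (maxlen - cfg$min_window + 1))
  end <- start + as.integer(len) - 1L
  season <- 1 + cfg$seasonal_amplitude *
    sin(2 * pi * (0:(span - 1)) / cfg$seasonal_period)
  # drug adoption and Day Zero
  exposure <- list()
  dzmat <- matrix(NA_integer_, u_n, length(cfg$drugs),
                  dimnames = list(NULL, names(cfg$drugs)))
  for (d in names(cfg$drugs)) {
    expo <- stats::runif(u_n) < cfg$drugs[[d]]
    dz <- start + as.integer(floor(stats::runif(u_n) * (end - start + 1)))
    dzmat[expo, d] <- dz[expo]
    exposure[[d]] <- stats::setNames(dz[expo], users[expo])
  }
  n_exposed <- stats::setNames(colSums(!is.na(dzmat)), colnames(dzmat))
  # per-effect activation windows (rows aligned to affected users)
  sample_delay <- function(eff_row, k) {
    if (eff_row$onset == "geometric") {
      stats::rgeom(k, eff_row$onset_par1)
    } else {
      eff_row$onset_par1 +
        floor(stats::runif(k) *
                (eff_row$onset_par2 - eff_row$onset_par1 + 1))
    }
  }
  activations <- list()  # per symptom: list of (users idx, e_start, e_end, mult)
  add_activation <- function(sym, idx, dz0, eff_row) {
    if (!length(idx)) return()
    delay <- sample_delay(eff_row, length(idx))
    e_start <- dz0 + delay
    e_end <- if (is.finite(eff_row$duration)) {
      e_start + eff_row$duration - 1
    } else {
      rep(Inf, length(idx))
    }
    activations[[sym]][[length(activations[[sym]]) + 1L]] <<-
      list(idx = idx, e_start = e_start, e_end = e_end,
           mult = eff_row$multiplier)
  }
  for (s in names(cfg$symptoms)) activations[[s]] <- list()
  if (!is.null(cfg$effects)) {
    for (r in seq_len(nrow(cfg$effects))) {
      eff <- cfg$effects[r, ]
      idx <- which(!is.na(dzmat[, eff$drug]))
      add_activation(eff$symptom, idx, dzmat[idx, eff$drug], eff)
    }
  }
  if (!is.null(cfg$pair_effects)) {
    for (r in seq_len(nrow(cfg$pair_effects))) {
      eff <- cfg$pair_effects[r, ]
      idx <- which(!is.na(dzmat[, eff$drug_i]) & !is.na(dzmat[, eff$drug_j]))
      add_activation(eff$symptom, idx,
                     pmax(dzmat[idx, eff$drug_i], dzmat[idx, eff$drug_j]),
                     eff)
    }
  }
  # base day-weight matrix: season within each user's window
  daym <- matrix(0:(span - 1), u_n, span, byrow = TRUE)
  wbase <- (daym >= start & daym <= end) *
    matrix(season, u_n, span, byrow = TRUE)
  wbase_sum <- rowSums(wbase)
  ev_user <- list(); ev_day <- list(); ev_term <- list()
  k <- 0L
  for (s in names(cfg$symptoms)) {
    rate <- cfg$symptoms[[s]]
    acts <- activations[[s]]
    if (length(acts)) {
      w <- wbase
      for (a in acts) {
        sub <- w[a$idx, , drop = FALSE]
        dsub <- daym[a$idx, , drop = FALSE]
        hit <- dsub >= a$e_start & dsub <= a$e_end
        sub[hit] <- sub[hit] * a$mult
        w[a$idx, ] <- sub
      }
      lam <- rate * rowSums(w)
    } else {
      w <- wbase
      lam <- rate * wbase_sum
    }
    counts <- stats::rpois(u_n, lam)
    nz <- which(counts > 0)
    for (u in nz) {
      kk <- counts[u]
      days <- sample.int(span, kk, replace = TRUE, prob = w[u, ]) - 1L
      k <- k + 1L
      ev_user[[k]] <- rep.int(u, kk)
      ev_day[[k]] <- days
      ev_term[[k]] <- rep.int(s, kk)
    }
  }
  # drug query events (one per exposed user, on Day Zero)
  for (d in names(cfg$drugs)) {
    idx <- which(!is.na(dzmat[, d]))
    if (length(idx)) {
      k <- k + 1L
      ev_user[[k]] <- idx
      ev_day[[k]] <- dzmat[idx, d]
      ev_term[[k]] <- rep.int(d, length(idx))
    }
  }
  if (k == 0L) {
    return(list(log = .empty_log(), truth = truth_base(exposure, n_exposed)))
  }
  ev <- data.frame(user = users[unlist(ev_user, use.names = FALSE)],
                   day = as.integer(unlist(ev_day, use.names = FALSE)),
                   term = unlist(ev_term, use.names = FALSE),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$user, ev$day, ev$term), , drop = FALSE]
  ev$event <- seq_len(nrow(ev))
  list(log = query_log(ev, span = span),
       truth = truth_base(exposure, n_exposed))
}

#' Simulate a spontaneous-report count table
#'
#' Background noise in every (drug, symptom) cell plus planted-effect
#' reports whose expectation follows the [sim_reporting()] model: exposure
#' times effect size times an acuteness-weighted reporting probability that
#' decays exponentially with the effect's mean onset delay. This builds the
#' acuteness bias of spontaneous reporting into the reference database:
#' early-onset reactions are over-represented relative to their query-log
#' footprint, late-onset ones under-represented.
#'
#' @param cfg a [sim_config()].
#' @param truth ground truth from [simulate_query_log()].
#' @return A [report_counts()] object.
#' @export
simulate_reports <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_ground_truth"))
  rep_cfg <- cfg$reporting
  withr::with_seed(derive_seed(cfg$seed, 104729L), {
    m <- matrix(stats::rpois(length(cfg$drugs) * length(cfg$symptoms),
                             rep_cfg$background),
                length(cfg$drugs), length(cfg$symptoms),
                dimnames = list(names(cfg$drugs), names(cfg$symptoms)))
    eff <- truth$effects
    if (!is.null(eff) && nrow(eff)) {
      for (r in seq_len(nrow(eff))) {
        mu <- truth$n_exposed[[eff$drug[r]]] *
          (eff$multiplier[r] - 1) * rep_cfg$per_exposed *
          eff$acuteness[r] * exp(-eff$mean_delay[r] / rep_cfg$decay_days)
        m[eff$drug[r], eff$symptom[r]] <-
          m[eff$drug[r], eff$symptom[r]] + stats::rpois(1, mu)
      }
    }
    report_counts(m)
  })
}

#' Simulate a known-ADR label set
#'
#' Positives are the planted single-drug ADRs; a configurable fraction can
#' be dropped at random to emulate the incompleteness of package-insert
#' references.
#'
#' @param truth ground truth from [simulate_query_log()].
#' @param drop_fraction probability each planted ADR is missing from the
#'   labels (default 0).
#' @param seed RNG seed for the drop draw (derived from the simulation seed
#'   by default).
#' @return A [label_set()].
#' @export
simulate_label_set <- function(truth, drop_fraction = 0,
                               seed = derive_seed(truth$seed, 7919L)) {
  stopifnot(inherits(truth, "sim_ground_truth"),
            drop_fraction >= 0, drop_fraction <= 1)
  eff <- truth$effects
  if (is.null(eff) || !nrow(eff)) {
    return(label_set(data.frame(drug = character(), symptom = character())))
  }
  keep <- withr::with_seed(seed,
                           stats::rbinom(nrow(eff), 1, 1 - drop_fraction) == 1)
  label_set(data.frame(drug = eff$drug[keep], symptom = eff$symptom[keep]))
}
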