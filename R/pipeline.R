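.pipeline_defaults <- list(
  seed = 1,
  qlrs = list(top_k = 50, positive_only = FALSE, boundary = "after"),
  compare = list(enabled = TRUE),
  mdadr = list(m = 5),
  pairs = list(enabled = FALSE)
)

.read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("missing input: config file ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  cfg <- utils::modifyList(.pipeline_defaults, config)
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config field `simulate` or `inputs` is required")
  }
  cfg
}

.sim_config_from_list <- function(sim, seed) {
  symptoms <- sim$symptoms
  if (is.null(symptoms)) {
    n <- sim$n_symptoms %||% 20
    rate <- sim$baseline_rate %||% 0.001
    symptoms <- stats::setNames(rep(rate, n), sprintf("symptom%02d", seq_len(n)))
  } else {
    symptoms <- unlist(symptoms)
  }
  eff <- sim$effects
  if (!is.null(eff)) eff <- as.data.frame(eff)
  peff <- sim$pair_effects
  if (!is.null(peff)) peff <- as.data.frame(peff)
  rep_cfg <- do.call(sim_reporting, as.list(sim$reporting %||% list()))
  sim_config(n_users = sim$n_users %||% stop("config field `simulate.n_users` is required"),
             span_days = sim$span_days %||% 180,
             drugs = unlist(sim$drugs %||% stop("config field `simulate.drugs` is required")),
             symptoms = symptoms,
             seasonal_amplitude = sim$seasonal_amplitude %||% 0.2,
             seasonal_period = sim$seasonal_period %||% 365,
             effects = eff, pair_effects = peff,
             reporting = rep_cfg,
             min_window = sim$min_window %||% 60,
             seed = seed)
}

#' Run the full surveillance pipeline
#'
#' Orchestrates simulate (or load) -> QLRS per drug -> comparison with the
#' report database -> MDADR identification -> optional drug-pair analysis,
#' writing one CSV per stage plus a JSON run manifest with the configuration
#' snapshot, seed, package version, per-stage row counts, timings and md5
#' digests of every artifact. Identical configuration and seed reproduce
#' byte-identical CSV outputs. Any stage failure aborts with a partial
#' manifest in place.
#'
#' @param config a list, or path to a JSON file, with fields `seed`,
#'   `simulate` (passed to [sim_config()]; or `inputs` with paths `log`,
#'   `dictionary`, `reports`, `labels`), `qlrs` (`top_k`, `positive_only`,
#'   `boundary`), `compare` (`enabled`), `mdadr` (`m`), `pairs` (`enabled`,
#'   `drug_i`, `drug_j`).
#' @param out_dir output directory (created if absent).
#' @param seed overrides the config seed when non-NULL.
#' @return invisibly, a list with `out_dir`, `manifest` and the per-stage
#'   artifact paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- .read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    tool_version = as.character(utils::packageVersion("querywatch")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), digests = list())
  paths <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         force = TRUE)
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(proc.time()[["elapsed"]] - t0, 3)),
                                  res$meta)
    res$value
  }
  # --- inputs -------------------------------------------------------------
  state <- stage("inputs", function() {
    if (!is.null(cfg$simulate)) {
      scfg <- .sim_config_from_list(cfg$simulate, cfg$seed)
      sim <- simulate_query_log(scfg)
      rc <- simulate_reports(scfg, sim$truth)
      labels <- simulate_label_set(sim$truth,
                                   cfg$simulate$label_drop %||% 0)
      paths$log <<- file.path(out_dir, "log.tsv")
      write_query_log(sim$log, paths$log)
      paths$reports <<- file.path(out_dir, "reports.csv")
      write_report_counts(rc, paths$reports)
      paths$labels <<- file.path(out_dir, "labels.csv")
      write_label_set(labels, paths$labels)
      paths$truth <<- file.path(out_dir, "truth.json")
      jsonlite::write_json(
        list(effects = sim$truth$effects,
             pair_effects = sim$truth$pair_effects,
             n_exposed = as.list(sim$truth$n_exposed), seed = sim$truth$seed),
        paths$truth, auto_unbox = TRUE, pretty = TRUE, null = "null")
      list(value = list(log = sim$log, rc = rc, labels = labels,
                        drugs = names(scfg$drugs),
                        symptoms = names(scfg$symptoms)),
           meta = list(n_records = sim$log$n_records,
                       n_users = length(unique(sim$log$events$user))))
    } else {
      inp <- cfg$inputs
      for (f in c("log", "dictionary")) {
        if (is.null(inp[[f]])) stop("missing input: `inputs.", f, "`")
        if (!file.exists(inp[[f]])) stop("missing input: ", inp[[f]])
      }
      dict <- load_term_dictionary(inp$dictionary)
      log <- read_query_log(inp$log, dict)
      rc <- NULL
      if (!is.null(inp$reports)) {
        if (!file.exists(inp$reports)) stop("missing input: ", inp$reports)
        rc <- read_report_counts(inp$reports)
      }
      labels <- NULL
      if (!is.null(inp$labels) && file.exists(inp$labels)) {
        labels <- read_label_set(inp$labels)
      }
      list(value = list(log = log, rc = rc, labels = labels,
                        drugs = cfg$drugs %||% dict$drugs,
                        symptoms = dict$symptoms),
           meta = list(n_records = log$n_records))
    }
  })
  if (isTRUE(cfg$compare$enabled) && is.null(state$rc)) {
    manifest$stages[["compare"]] <- list(status = "failed",
                                         error = "missing input: `inputs.reports` (compare enabled)")
    write_manifest()
    stop("missing input: `inputs.reports` is required when compare is enabled",
         call. = FALSE)
  }
  # --- qlrs ---------------------------------------------------------------
  fits <- stage("qlrs", function() {
    fits <- list()
    for (d in state$drugs) {
      fit <- tryCatch(suppressWarnings(
        qlrs(state$log, d, symptoms = state$symptoms,
             top_k = cfg$qlrs$top_k,
             positive_only = cfg$qlrs$positive_only,
             boundary = cfg$qlrs$boundary)),
        error = function(e) NULL)
      if (!is.null(fit) && nrow(fit$scores)) fits[[d]] <- fit
    }
    if (!length(fits)) stop("no drug produced a QLRS ranking")
    df <- do.call(rbind, lapply(fits, as.data.frame))
    p <- file.path(out_dir, "qlrs.csv")
    utils::write.csv(df, p, row.names = FALSE)
    paths$qlrs <<- p
    list(value = fits, meta = list(n_drugs = length(fits), n_rows = nrow(df)))
  })
  # --- compare ------------------------------------------------------------
  comparisons <- NULL
  if (isTRUE(cfg$compare$enabled)) {
    comparisons <- stage("compare", function() {
      prior <- suppressWarnings(
        tryCatch(fit_ebgm(state$rc),
                 ebgm_convergence_error = function(e) e$best,
                 error = function(e) ebgm_prior(0.2, 0.1, 2, 4, 1 / 3)))
      rows <- list()
      for (d in names(fits)) {
        # degenerate references (e.g. IC against a one-drug table) yield NA
        # columns rather than aborting the stage
        rows[[d]] <- tryCatch(suppressWarnings(
          compare_rankings(fits[[d]], state$rc, prior = prior)),
          error = function(e) NULL)
      }
      df <- do.call(rbind, rows)
      if (is.null(df)) stop("no drug could be compared with the report table")
      meta_row <- meta_combine(data.frame(rho = df$rho1, n = df$n))
      p <- file.path(out_dir, "compare.csv")
      utils::write.csv(df, p, row.names = FALSE)
      paths$compare <<- p
      list(value = list(table = df, meta_rho1 = meta_row),
           meta = list(n_drugs = nrow(df),
                       pooled_rho1 = round(meta_row$rho, 4)))
    })
  }
  # --- mdadr --------------------------------------------------------------
  if (!is.null(state$rc)) {
    stage("mdadr", function() {
      rows <- list()
      for (d in names(fits)) {
        if (!d %in% state$rc$drugs) next
        q <- stats::setNames(fits[[d]]$scores$qlrs, fits[[d]]$scores$symptom)
        ref <- state$rc$counts[d, ]
        md <- tryCatch(greedy_mdadr(q, ref, m = cfg$mdadr$m, drug = d),
                       error = function(e) NULL)
        if (is.null(md) || !nrow(md$removed)) next
        r <- md$removed
        r$drug <- d
        r$step <- seq_len(nrow(r))
        r$rho_before <- md$rho_before
        rows[[d]] <- r
      }
      df <- do.call(rbind, rows)
      if (is.null(df)) {
        df <- data.frame(symptom = character(), rho_after = numeric(),
                         qlrs_rank = numeric(), ref_rank = numeric(),
                         direction = character(), drug = character(),
                         step = integer(), rho_before = numeric())
      }
      p <- file.path(out_dir, "mdadr.csv")
      utils::write.csv(df[, c("drug", "step", "symptom", "rho_before",
                              "rho_after", "qlrs_rank", "ref_rank",
                              "direction")],
                       p, row.names = FALSE)
      paths$mdadr <<- p
      list(value = df, meta = list(n_rows = nrow(df)))
    })
  }
  # --- pairs --------------------------------------------------------------
  if (isTRUE(cfg$pairs$enabled)) {
    stage("pairs", function() {
      if (is.null(cfg$pairs$drug_i) || is.null(cfg$pairs$drug_j)) {
        stop("config fields `pairs.drug_i` and `pairs.drug_j` are required")
      }
      fit <- drug_interaction(state$log, cfg$pairs$drug_i, cfg$pairs$drug_j,
                              symptoms = state$symptoms)
      p <- file.path(out_dir, "pairs.csv")
      utils::write.csv(fit$table[order(-fit$table$std_residual), ], p,
                       row.names = FALSE)
      paths$pairs <<- p
      list(value = fit, meta = list(n_symptoms = fit$n))
    })
  }
  manifest$digests <- as.list(tools::md5sum(unlist(paths)))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  write_manifest()
  invisible(list(out_dir = out_dir, manifest = manifest, paths = paths,
                 fits = fits, comparisons = comparisons))
}
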