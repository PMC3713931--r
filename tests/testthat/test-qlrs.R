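test_that("Day Zero is first drug query for exposed, midpoint otherwise", {
  lg <- log_from_events(
    user = c("e", "e", "e", "m", "m", "s"),
    day = c(14, 9, 20, 10, 30, 7),
    term = c("druga", "druga", "nausea", "nausea", "rash", "nausea"),
    span = 40)
  dz <- assign_day_zero(lg, "druga")
  expect_equal(dz$day_zero[dz$user == "e"], 9L)
  expect_true(dz$exposed[dz$user == "e"])
  expect_equal(dz$day_zero[dz$user == "m"], 20L)
  expect_false(dz$exposed[dz$user == "m"])
  # single-event user: degenerate midpoint is the event day
  expect_equal(dz$day_zero[dz$user == "s"], 7L)
})

test_that("top-symptom selection counts exposed users only, ties lexicographic", {
  lg <- log_from_events(
    user = c("e1", "e1", "e1", "e1", "e1", "u1", "u1"),
    day = c(0, 1, 2, 3, 4, 1, 2),
    term = c("druga", "nausea", "nausea", "nausea", "rash", "apnea", "apnea"),
    span = 10)
  expect_equal(select_top_symptoms(lg, "druga"), c("nausea", "rash"))
  # tie at k = 1 resolves lexicographically
  lg2 <- log_from_events(user = c("e", "e", "e"), day = c(0, 1, 2),
                         term = c("druga", "b", "a"), span = 10)
  expect_equal(select_top_symptoms(lg2, "druga", k = 1), "a")
  # full-sort oracle on 60 distinct counts
  cnt <- sample(60) + 60
  terms <- sprintf("t%02d", 1:60)
  lg3 <- log_from_events(
    user = "e", day = c(0, rep(1, sum(cnt))),
    term = c("druga", rep(terms, cnt)), span = 10)
  got <- select_top_symptoms(lg3, "druga", k = 50)
  oracle <- terms[order(-cnt, terms)][1:50]
  expect_equal(got, oracle)
  expect_warning(select_top_symptoms(lg, "nosuchdrug"), "no users")
})

test_that("contingency cells follow the exposed/before-after classification", {
  # one exposed user with symptom at dz-2 and dz+5
  lg <- log_from_events(user = c("e", "e", "e", "u"),
                        day = c(10, 8, 15, 5),
                        term = c("druga", "nausea", "nausea", "headache"),
                        span = 30)
  tab <- build_contingency(lg, "druga", "nausea")
  expect_equal(as.vector(tab), c(0L, 0L, 1L, 1L))  # N11,N21,N12,N22
  # event exactly on Day Zero counts as "after" by default...
  lg2 <- log_from_events(user = c("e", "e"), day = c(10, 10),
                         term = c("druga", "nausea"), span = 30)
  expect_equal(build_contingency(lg2, "druga", "nausea")["after", "yes"], 1L)
  # ...and as "before" under the flipped convention
  expect_equal(build_contingency(lg2, "druga", "nausea",
                                 boundary = "before")["before", "yes"], 1L)
})

test_that("a mixed fixture matches an event-by-event classification oracle", {
  set.seed(31)
  users <- c("e1", "e2", "u1", "u2")
  ev <- data.frame(
    user = sample(users, 60, replace = TRUE),
    day = sample(0:29, 60, replace = TRUE),
    term = sample(c("nausea", "rash"), 60, replace = TRUE))
  drug_ev <- data.frame(user = c("e1", "e2"), day = c(12, 4), term = "druga")
  lg <- log_from_events(user = c(ev$user, drug_ev$user),
                        day = c(ev$day, drug_ev$day),
                        term = c(ev$term, drug_ev$term), span = 30)
  dz <- assign_day_zero(lg, "druga")
  tab <- build_contingency(lg, "druga", "nausea", dz = dz)
  # oracle: classify each nausea event independently
  oracle <- matrix(0L, 2, 2)
  for (i in which(ev$term == "nausea")) {
    row <- dz[dz$user == ev$user[i], ]
    oracle[1 + (ev$day[i] >= row$day_zero), 1 + row$exposed] <-
      oracle[1 + (ev$day[i] >= row$day_zero), 1 + row$exposed] + 1L
  }
  expect_equal(unname(unclass(tab)), oracle)
  # all four cells sum to the number of symptom events
  expect_equal(sum(tab), sum(ev$term == "nausea"))
})

test_that("qlrs_score equals the textbook Pearson statistic", {
  tab <- matrix(c(10, 30, 20, 40), 2, 2)  # N11,N21,N12,N22
  s <- qlrs_score(tab)
  expect_equal(s$statistic, 4 / 12 + 4 / 18 + 4 / 28 + 4 / 42)
  expect_equal(s$statistic, 50 / 63, tolerance = 1e-12)
  # perfect independence
  expect_equal(qlrs_score(matrix(5, 2, 2))$statistic, 0)
  # zero "before" margin -> degenerate, score 0
  expect_equal(qlrs_score(matrix(c(0, 3, 0, 7), 2, 2))$statistic, 0)
  expect_error(qlrs_score(matrix(0, 2, 2)), "empty table")
})

test_that("qlrs_score direction tracks the N22 excess and the statistic is symmetric", {
  up <- matrix(c(50, 40, 50, 80), 2, 2)
  down <- matrix(c(50, 80, 50, 40), 2, 2)
  expect_equal(qlrs_score(up)$direction, 1L)
  expect_equal(qlrs_score(down)$direction, -1L)
  # swapping rows together with columns leaves the statistic unchanged
  set.seed(8)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    flipped <- tab[2:1, 2:1]
    expect_equal(qlrs_score(tab)$statistic, qlrs_score(flipped)$statistic)
  }
})

test_that("qlrs_score matches chisq.test without continuity correction", {
  set.seed(99)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(5, 50, 500), 1)) + 1, 2, 2)
    expect_equal(qlrs_score(tab)$statistic,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)),
                 tolerance = 1e-9)
  }
})

test_that("qlrs() ranks a planted ADR first and errors with no exposure", {
  cfg <- small_world(n_users = 3000, n_symptoms = 30, planted = "s01",
                     seed = 7)
  sim <- simulate_query_log(cfg)
  fit <- qlrs(sim$log, "druga", symptoms = names(cfg$symptoms), top_k = 30)
  expect_s3_class(fit, "qlrs")
  expect_equal(fit$scores$symptom[1], "s01")
  expect_equal(fit$scores$direction[1], 1L)
  expect_true(all(diff(fit$scores$qlrs) <= 0))
  expect_error(qlrs(sim$log, "nosuchdrug"), "no users")
  # candidate list respects direction and threshold
  cand <- candidate_adrs(fit, threshold = qchisq(0.95, 1))
  expect_true(all(cand$direction > 0))
  expect_true(all(cand$qlrs >= qchisq(0.95, 1)))
})

test_that("null worlds rarely produce significant scores", {
  tails <- vapply(1:8, function(r) {
    cfg <- small_world(n_users = 600, n_symptoms = 25, seed = 500 + r)
    sim <- simulate_query_log(cfg)
    fit <- qlrs(sim$log, "druga", symptoms = names(cfg$symptoms),
                top_k = 25, positive_only = FALSE)
    mean(fit$scores$qlrs > qchisq(0.95, 1))
  }, numeric(1))
  expect_lt(mean(tails), 0.12)
})

test_that("brand tables aggregate cell-wise into generics", {
  a <- matrix(c(1, 3, 2, 4), 2, 2)
  b <- matrix(c(10, 30, 20, 40), 2, 2)
  out <- aggregate_brands(list(brandA = a, brandB = b),
                          c(brandA = "gen", brandB = "gen"))
  expect_equal(out$gen, matrix(c(11, 33, 22, 44), 2, 2))
  # single-brand generic is the identity
  out1 <- aggregate_brands(list(brandA = a), c(brandA = "gen"))
  expect_equal(out1$gen, a)
  # three brands, hand-summed oracle; unmapped brand keeps its own name
  cc <- matrix(c(5, 6, 7, 8), 2, 2)
  out3 <- aggregate_brands(list(x = a, y = b, z = cc),
                           c(x = "g1", y = "g1"))
  expect_equal(out3$g1, a + b)
  expect_equal(out3$z, cc)
  expect_error(aggregate_brands(list()), "empty")
})

test_that("aggregating brands commutes with merging disjoint populations", {
  mk <- function(drug, seed) {
    symptoms <- c(nausea = 0.005, rash = 0.005)
    simulate_query_log(sim_config(n_users = 300,
                                  drugs = stats::setNames(0.4, drug),
                                  symptoms = symptoms, seed = seed))$log
  }
  la <- mk("branda", 1)
  lb <- mk("brandb", 2)
  ta <- build_contingency(la, "branda", "nausea")
  tb <- build_contingency(lb, "brandb", "nausea")
  summed <- aggregate_brands(list(branda = ta, brandb = tb),
                             c(branda = "gen", brandb = "gen"))$gen
  # merge the two disjoint user populations, renaming brands to the generic
  ea <- la$events; ea$user <- paste0("a_", ea$user)
  eb <- lb$events; eb$user <- paste0("b_", eb$user)
  merged <- rbind(ea[c("user", "day", "term")], eb[c("user", "day", "term")])
  merged$term[merged$term %in% c("branda", "brandb")] <- "gen"
  lg <- log_from_events(merged$user, merged$day, merged$term,
                        span = max(la$span, lb$span))
  direct <- build_contingency(lg, "gen", "nausea")
  expect_equal(unclass(summed), unclass(direct), ignore_attr = TRUE)
})
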