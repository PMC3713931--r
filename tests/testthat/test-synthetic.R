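test_that("sim_config validates fields with named errors", {
  expect_error(sim_config(-1, drugs = c(a = .1), symptoms = c(s = .01)),
               "n_users")
  expect_error(sim_config(10, drugs = c(1.2), symptoms = c(s = .01)),
               "drugs")
  expect_error(sim_config(10, drugs = c(a = 2), symptoms = c(s = .01)),
               "drugs")
  expect_error(sim_config(10, drugs = c(a = .1), symptoms = c(s = -1)),
               "symptoms")
  expect_error(sim_config(10, drugs = c(a = .1), symptoms = c(s = .01),
                          seasonal_amplitude = 1), "seasonal_amplitude")
  expect_error(sim_config(10, drugs = c(a = .1), symptoms = c(s = .01),
                          effects = adr_effect("b", "s", 2)), "unknown drug")
  expect_error(sim_config(10, drugs = c(a = .1), symptoms = c(s = .01),
                          effects = adr_effect("a", "t", 2)),
               "unknown symptom")
})

test_that("identical config and seed give identical outputs", {
  cfg <- small_world(n_users = 300, n_symptoms = 6, planted = "s01", seed = 77)
  a <- simulate_query_log(cfg)
  b <- simulate_query_log(cfg)
  expect_identical(a$log$events, b$log$events)
  ra <- simulate_reports(cfg, a$truth)
  rb <- simulate_reports(cfg, b$truth)
  expect_identical(ra$counts, rb$counts)
  la <- simulate_label_set(a$truth, drop_fraction = 0.3)
  lb <- simulate_label_set(b$truth, drop_fraction = 0.3)
  expect_identical(as.data.frame(la), as.data.frame(lb))
  # and a different seed changes the log
  cfg2 <- small_world(n_users = 300, n_symptoms = 6, planted = "s01",
                      seed = 78)
  expect_false(identical(simulate_query_log(cfg2)$log$events, a$log$events))
})

test_that("zero users give an empty world", {
  cfg <- small_world(n_users = 0, n_symptoms = 3)
  sim <- simulate_query_log(cfg)
  expect_equal(nrow(sim$log$events), 0)
  expect_equal(unname(sim$truth$n_exposed), 0L)
})

test_that("a unit multiplier leaves before/after rates equal", {
  # single high-rate symptom, full-span windows, no seasonality: the
  # before/after split of an unexposed user should be rate-neutral
  cfg <- sim_config(n_users = 1, span_days = 180, drugs = c(druga = 0),
                    symptoms = c(s = 10), seasonal_amplitude = 0,
                    min_window = 180, seed = 4)
  sim <- simulate_query_log(cfg)
  ev <- sim$log$events
  dz <- assign_day_zero(sim$log, "druga")
  nb <- sum(ev$day < dz$day_zero)
  na_ <- sum(ev$day >= dz$day_zero)
  days_b <- dz$day_zero - min(ev$day)
  days_a <- max(ev$day) - dz$day_zero + 1
  pt <- stats::poisson.test(c(nb, na_), c(days_b, days_a))
  expect_gt(pt$p.value, 0.01)
})

test_that("a planted multiplier of 5 yields a ~5x post-Day-Zero rate", {
  cfg <- sim_config(n_users = 5000, span_days = 180,
                    drugs = c(druga = 0.3),
                    symptoms = c(nausea = 0.02),
                    seasonal_amplitude = 0, min_window = 180,
                    effects = adr_effect("druga", "nausea", 5,
                                         onset = "geometric",
                                         onset_par1 = 0.9),
                    seed = 123)
  sim <- simulate_query_log(cfg)
  dzs <- sim$truth$exposure$druga   # user -> first-search day
  ev <- sim$log$events
  ev <- ev[ev$term == "nausea" & ev$user %in% names(dzs), ]
  dz <- dzs[ev$user]
  # full-span windows: person-days before = dz, after = 180 - dz
  rate_before <- sum(ev$day < dz) / sum(dzs)
  rate_after <- sum(ev$day >= dz) / sum(180 - dzs)
  ratio <- rate_after / rate_before
  expect_gt(ratio, 4)
  expect_lt(ratio, 6)
})

test_that("report counts follow the acuteness-biased reporting model", {
  # zero reporting probability: planted cells are background only
  eff <- rbind(adr_effect("druga", "s01", 5),
               adr_effect("druga", "s02", 5, onset = "uniform",
                          onset_par1 = 0, onset_par2 = 0))
  cfg0 <- sim_config(n_users = 500, drugs = c(druga = 0.5),
                     symptoms = c(s01 = .001, s02 = .001, s03 = .001),
                     effects = eff,
                     reporting = sim_reporting(per_exposed = 0,
                                               background = 0), seed = 5)
  sim0 <- simulate_query_log(cfg0)
  rc0 <- simulate_reports(cfg0, sim0$truth)
  expect_equal(sum(rc0$counts), 0)  # no background, no effects reported

  # early-onset beats late-onset for otherwise identical ADRs
  eff2 <- rbind(adr_effect("druga", "s01", 5, onset = "uniform",
                           onset_par1 = 0, onset_par2 = 0),
                adr_effect("druga", "s02", 5, onset = "uniform",
                           onset_par1 = 60, onset_par2 = 60))
  cfg2 <- sim_config(n_users = 2000, drugs = c(druga = 0.5),
                     symptoms = c(s01 = .001, s02 = .001, s03 = .001),
                     effects = eff2,
                     reporting = sim_reporting(per_exposed = 0.1,
                                               decay_days = 20,
                                               background = 0), seed = 6)
  sim2 <- simulate_query_log(cfg2)
  rc2 <- simulate_reports(cfg2, sim2$truth)
  expect_gt(rc2$counts["druga", "s01"], rc2$counts["druga", "s02"])
  # unplanted cell has no reports without background
  expect_equal(unname(rc2$counts["druga", "s03"]), 0)
})

test_that("label sets mirror the planted truth, with seeded dropout", {
  cfg <- small_world(n_users = 50, n_symptoms = 12,
                     planted = sprintf("s%02d", 1:10), seed = 30)
  sim <- simulate_query_log(cfg)
  expect_equal(nrow(simulate_label_set(sim$truth)), 10)
  # no planted ADRs -> empty labels
  cfg0 <- small_world(n_users = 50, n_symptoms = 3, seed = 30)
  sim0 <- simulate_query_log(cfg0)
  expect_equal(nrow(simulate_label_set(sim0$truth)), 0)
  # dropout equals an independent seeded binomial draw
  ls <- simulate_label_set(sim$truth, drop_fraction = 0.2, seed = 99)
  oracle_keep <- withr::with_seed(99, stats::rbinom(10, 1, 0.8) == 1)
  expect_equal(nrow(ls), sum(oracle_keep))
  expect_identical(ls, simulate_label_set(sim$truth, drop_fraction = 0.2,
                                          seed = 99))
})
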