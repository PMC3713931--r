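test_that("greedy MDADR reproduces the worked example", {
  q <- c(s1 = 10, s2 = 8, s3 = 6, s4 = 4, s5 = 2)
  r <- c(s1 = 100, s2 = 80, s3 = 5, s4 = 40, s5 = 20)
  md <- greedy_mdadr(q, r, m = 1)
  expect_equal(md$rho_before, 0.7)          # d^2 = 6, n = 5
  expect_equal(md$removed$symptom, "s3")
  expect_equal(md$removed$rho_after, 1)
  expect_equal(md$removed$direction, "overemphasized_querylog")
})

test_that("greedy MDADR tie and degenerate cases", {
  # perfectly concordant: any removal leaves rho = 1; lexicographically
  # smallest symptom removed
  q <- c(b = 4, a = 3, d = 2, c = 1, e = 0.5)
  md <- greedy_mdadr(q, q * 2 + 1, m = 1)
  expect_equal(md$removed$symptom, "a")
  expect_equal(md$removed$rho_after, 1)
  # m = 0: nothing removed
  md0 <- greedy_mdadr(q, q, m = 0)
  expect_equal(nrow(md0$removed), 0)
  expect_equal(md0$rho_before, 1)
  expect_error(greedy_mdadr(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3),
                            m = 2), "m \\+ 3")
})

test_that("each greedy step is rho-maximal and matches exhaustive search", {
  # Note: the trajectory itself can occasionally decrease — for some score
  # pairs every single removal lowers the Spearman correlation — so the
  # invariant asserted here is the true greedy one: the removal at each
  # step attains the maximum over all available single removals.
  set.seed(17)
  for (i in 1:30) {
    n <- sample(6:10, 1)
    syms <- sprintf("s%02d", 1:n)
    q <- stats::setNames(sample(100, n), syms)
    r <- stats::setNames(sample(100, n), syms)
    md <- greedy_mdadr(q, r, m = 3)
    # independent single-step oracle using the reference implementation
    remaining <- sort(syms)
    for (step in 1:3) {
      rhos <- vapply(remaining, function(s) {
        rest <- setdiff(remaining, s)
        cor(q[rest], r[rest], method = "spearman")
      }, numeric(1))
      best <- max(rhos)
      expect_equal(md$removed$rho_after[step], best, tolerance = 1e-12)
      winners <- names(rhos)[rhos > best - 1e-12]
      # compare the choice only when the greedy choice is unique
      if (length(winners) == 1) {
        expect_equal(md$removed$symptom[step], winners)
      }
      remaining <- setdiff(remaining, md$removed$symptom[step])
    }
  }
})

test_that("discordance direction is antisymmetric in the two rankings", {
  expect_equal(classify_discordance(15, 2), "overemphasized_reference")
  expect_equal(classify_discordance(3, 20), "overemphasized_querylog")
  expect_equal(classify_discordance(4, 4), "undetermined")
  set.seed(3)
  a <- sample(20); b <- sample(20)
  d1 <- classify_discordance(a, b)
  d2 <- classify_discordance(b, a)
  swap <- c(overemphasized_querylog = "overemphasized_reference",
            overemphasized_reference = "overemphasized_querylog",
            undetermined = "undetermined")
  expect_equal(unname(swap[d1]), d2)
})

test_that("temporal profiles collect first post-Day-Zero onsets", {
  # one user, symptom first queried at dz + 10 (an earlier pre-dz query
  # must not count)
  lg <- log_from_events(user = rep("e", 4), day = c(5, 2, 15, 20),
                        term = c("druga", "nausea", "nausea", "nausea"),
                        span = 40)
  tp <- temporal_profile(lg, "druga", "nausea", horizon = 20)
  expect_equal(unname(tp$first_onset_days["e"]), 10)
  expect_equal(tp$cdf[1:10], rep(0, 10))   # offsets 0..9
  expect_equal(tp$cdf[11:21], rep(1, 11))  # offsets 10..20
  # exposed user who never queries the symptom: cdf stays 0
  lg2 <- log_from_events(user = c("e", "e"), day = c(5, 6),
                         term = c("druga", "rash"), span = 40)
  tp2 <- temporal_profile(lg2, "druga", "nausea", horizon = 10)
  expect_true(all(tp2$cdf == 0))
  expect_error(temporal_profile(lg2, "drugb", "nausea"), "no exposed")
  # cdf is monotone and bounded for any profile
  expect_true(all(diff(tp$cdf) >= 0) && max(tp$cdf) <= 1)
})

test_that("uniform onset delays give an approximately linear cdf", {
  set.seed(88)
  n <- 100
  onset <- floor(runif(n) * 51)  # uniform on 0..50
  users <- sprintf("u%03d", 1:n)
  lg <- log_from_events(user = c(users, users),
                        day = c(rep(0, n), onset),
                        term = c(rep("druga", n), rep("nausea", n)),
                        span = 60)
  tp <- temporal_profile(lg, "druga", "nausea", horizon = 59)
  analytic <- pmin((0:59 + 1) / 51, 1)
  expect_lt(max(abs(tp$cdf - analytic)), 0.1)  # KS distance
})

test_that("onset difference test handles degenerate and paired inputs", {
  x <- c(10, 12, 9, 14, 11)
  r0 <- onset_difference_test(x, x)
  expect_equal(r0$mean_difference, 0)
  expect_equal(r0$p.value, 1)
  expect_error(onset_difference_test(5, 3), "at least 5")
  set.seed(2)
  late <- rnorm(12, mean = 40, sd = 5)
  acute <- rnorm(12, mean = 5, sd = 2)
  r <- onset_difference_test(late, acute)
  expect_gt(r$mean_difference, 20)
  expect_lt(r$p.value, 0.01)
})

test_that("AUC and F score against a binary reference", {
  scores <- stats::setNames(10:1, sprintf("s%02d", 1:10))
  # positives exactly the top half
  ev <- evaluate_against_positives(scores, sprintf("s%02d", 1:5),
                                   threshold = 5.5)
  expect_equal(ev$auc, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$f_score, 1)
  # one positive ranked last
  ev2 <- evaluate_against_positives(scores, "s10")
  expect_equal(ev2$auc, 0)
  expect_error(evaluate_against_positives(scores, character(0)),
               "positive")
  expect_error(evaluate_against_positives(scores, names(scores)),
               "negative")
})

test_that("AUC is 0.5 on average under label permutation and rank-invariant", {
  set.seed(77)
  scores <- stats::setNames(rnorm(30), sprintf("s%02d", 1:30))
  aucs <- replicate(500, {
    pos <- sample(names(scores), 10)
    evaluate_against_positives(scores, pos)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  # invariance under strictly monotone transform
  pos <- sprintf("s%02d", c(2, 9, 17))
  a1 <- evaluate_against_positives(scores, pos)$auc
  a2 <- evaluate_against_positives(exp(scores * 3), pos)$auc
  expect_equal(a1, a2)
})
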