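test_that("expected counts come from the margins", {
  # drug margin 40, symptom margin 50, total 1000 -> E = 2
  m <- matrix(0, 2, 2, dimnames = list(c("d1", "d2"), c("s1", "s2")))
  m["d1", "s1"] <- 20; m["d1", "s2"] <- 20
  m["d2", "s1"] <- 30; m["d2", "s2"] <- 930
  rc <- report_counts(m)
  expect_equal(expected_count(rc, "d1", "s1"), 40 * 50 / 1000)
  # symptom absent from the database
  expect_equal(expected_count(rc, "d1", "nosuch"), 0)
  # random 5x5 matrix vs explicit margin sums
  set.seed(4)
  m5 <- matrix(rpois(25, 10), 5, 5,
               dimnames = list(paste0("d", 1:5), paste0("s", 1:5)))
  rc5 <- report_counts(m5)
  e5 <- expected_counts(rc5)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(e5[i, j], sum(m5[i, ]) * sum(m5[, j]) / sum(m5))
  }
})

test_that("IC is the shrunken log2 ratio with the right limits", {
  expect_equal(ic_score(20, 2.0), log2(20.5 / 2.5))
  expect_equal(ic_score(7, 7), 0)
  expect_equal(ic_score(0, 0), 0)
  # strictly increasing in n, strictly decreasing in E
  n_grid <- seq(0, 50, by = 5)
  expect_true(all(diff(ic_score(n_grid, 3)) > 0))
  e_grid <- seq(0, 50, by = 5)
  expect_true(all(diff(ic_score(10, e_grid)) < 0))
})

test_that("ebgm_score matches the single-component closed form and limits", {
  # w ~ 1: mixture degenerates to exp(psi(a+n) - log(b+E))
  p <- ebgm_prior(2, 4, 2, 4, 0.5)
  expect_equal(ebgm_score(10, 5, p), exp(digamma(12) - log(9)))
  # large counts: shrinkage vanishes, EBGM -> n/E
  p0 <- ebgm_prior(0.2, 0.1, 2, 4, 1 / 3)
  expect_equal(ebgm_score(1000, 500, p0), 2, tolerance = 0.05)
  # n = 0 with a prior of mean <= 1 shrinks below 1
  p1 <- ebgm_prior(1, 1, 2, 4, 0.5)  # mean 0.75
  expect_lt(ebgm_score(0, 2, p1), 1)
  # shrinkage toward the prior: for n/E above the prior mean, EBGM < n/E
  expect_lt(ebgm_score(30, 5, p0), 6)
  expect_error(ebgm_score(3, 0, p0), "e_exp")
})

test_that("ebgm_score is monotone in the observed count", {
  p <- ebgm_prior(0.2, 0.1, 2, 4, 1 / 3)
  scores <- ebgm_score(0:40, 5, p)
  expect_true(all(diff(scores) > 0))
})

test_that("fit_ebgm recovers a self-consistent prior and validates input", {
  set.seed(12)
  e <- exp(rnorm(1500, 1, 0.8))
  pf <- fit_ebgm(list(n = round(e), e = e))  # lambda ~ 1 everywhere
  pm <- pf$w * pf$alpha1 / pf$beta1 + (1 - pf$w) * pf$alpha2 / pf$beta2
  expect_gt(pm, 0.8)
  expect_lt(pm, 1.25)
  expect_error(fit_ebgm(list(n = numeric(), e = numeric())), "empty")
  m <- matrix(c(3, 1, 2, 4), 2, 2,
              dimnames = list(c("d1", "d2"), c("s1", "s2")))
  expect_warning(try(fit_ebgm(report_counts(m)), silent = TRUE),
                 "nonempty cells")
})

test_that("spearman_rho handles the textbook cases", {
  expect_equal(spearman_rho(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3))$rho, 1)
  expect_equal(spearman_rho(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1))$rho, -1)
  r <- spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)  # 1 - 6*2/(4*15)
  expect_equal(r$n, 4)
  expect_error(spearman_rho(c(a = 1, b = 2), c(a = 1, b = 2)), "at least 3")
})

test_that("spearman tie handling matches the reference implementation", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, replace = TRUE) + rnorm(n, 0, 1e-9)
    y <- sample(1:8, n, replace = TRUE)
    expect_equal(spearman_rho(x, y)$rho,
                 cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(22)
  x <- rnorm(20); y <- rnorm(20)
  r0 <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, r0)
  expect_equal(spearman_rho(x, 3 * y + 10)$rho, r0)
})

test_that("meta_combine pools on the Fisher-z scale", {
  # identical studies return the common rho
  two <- data.frame(rho = c(0.5, 0.5), n = c(50, 50))
  expect_equal(meta_combine(two)$rho, 0.5, tolerance = 1e-12)
  # a single study returns its own rho and the matching z-based p
  one <- data.frame(rho = 0.4, n = 30)
  m1 <- meta_combine(one)
  expect_equal(m1$rho, 0.4, tolerance = 1e-12)
  expect_equal(m1$p.value, 2 * pnorm(-abs(atanh(0.4) * sqrt(27))))
  # hand-computed weighted combination
  st <- data.frame(rho = c(0.3, 0.6), n = c(30, 60))
  zbar <- (27 * atanh(0.3) + 57 * atanh(0.6)) / (27 + 57)
  expect_equal(meta_combine(st)$rho, tanh(zbar), tolerance = 1e-12)
  # n < 4 studies excluded with warning
  expect_warning(m <- meta_combine(data.frame(rho = c(0.5, 0.9),
                                              n = c(50, 3))), "excluded")
  expect_equal(m$k, 1)
  # DL random effects reduces to fixed when homogeneous
  expect_equal(meta_combine(two, method = "DL")$rho, 0.5, tolerance = 1e-12)
})

test_that("compare_rankings produces rho1/rho2/rho3 on shared symptoms", {
  cfg <- small_world(n_users = 2500, n_symptoms = 12,
                     planted = c("s01", "s02"), seed = 5)
  sim <- simulate_query_log(cfg)
  # two drugs in the report table so IC/EBGM have real margins
  rc1 <- simulate_reports(cfg, sim$truth)
  m <- rbind(rc1$counts, other = rpois(ncol(rc1$counts), 3))
  rownames(m) <- c("druga", "other")
  rc <- report_counts(m)
  fit <- qlrs(sim$log, "druga", symptoms = names(cfg$symptoms), top_k = 12)
  res <- compare_rankings(fit, rc, prior = ebgm_prior(0.2, 0.1, 2, 4, 1 / 3))
  expect_equal(res$n, 12)
  expect_true(all(abs(unlist(res[c("rho1", "rho2", "rho3")])) <= 1))
  # planted ADRs dominate both sources, so correlation should be positive
  expect_gt(res$rho1, 0)
})
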