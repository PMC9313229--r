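test_that("two-cluster stratification is the optimal within-SS partition", {
  set.seed(404)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    v <- setNames(runif(n), sprintf("P%02d", 1:n))
    got <- stratify_by_pair(v)
    members <- names(v) %in% got$large_ids
    oracle <- oracle_ward_2split(unname(v))
    w_got <- sum((v[members] - mean(v[members]))^2) +
      sum((v[!members] - mean(v[!members]))^2)
    expect_equal(w_got, oracle$wss, tolerance = 1e-9)
  }
})

test_that("the larger-mean cluster is labeled Large", {
  v <- setNames(c(rep(0.01, 10), rep(0.9, 5)), sprintf("P%02d", 1:15))
  s <- stratify_by_pair(v, pair = "A_B")
  expect_length(s$large_ids, 5)
  expect_length(s$small_ids, 10)
  expect_setequal(s$large_ids, sprintf("P%02d", 11:15))

  s2 <- stratify_by_pair(c(a = 0.1, b = 0.7))
  expect_equal(s2$large_ids, "b")
  expect_equal(s2$small_ids, "a")
})

test_that("stratification is input-order invariant and degenerate-safe", {
  v <- setNames(runif(12), sprintf("P%02d", 1:12))
  s1 <- stratify_by_pair(v)
  s2 <- stratify_by_pair(rev(v))
  expect_identical(s1$large_ids, s2$large_ids)
  expect_warning(out <- stratify_by_pair(setNames(rep(0.3, 5), letters[1:5])),
                 "identical")
  expect_null(out)
})

test_that("log-rank statistic matches an explicit risk-set tally", {
  # 6-patient toy, all events, clean group separation
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(TRUE, 6)
  grp <- c("A", "A", "A", "B", "B", "B")
  got <- logrank_test(time, event, grp)
  orc <- oracle_logrank(time, event, grp)
  expect_equal(got$statistic, orc$chisq, tolerance = 1e-9)
  expect_equal(got$p.value, orc$p, tolerance = 1e-9)

  # with censoring and ties
  set.seed(13)
  time2 <- sample(1:20, 30, replace = TRUE)
  event2 <- runif(30) < 0.7
  grp2 <- rep(c("A", "B"), 15)
  got2 <- logrank_test(time2, event2, grp2)
  orc2 <- oracle_logrank(time2, event2, grp2)
  expect_equal(got2$statistic, orc2$chisq, tolerance = 1e-9)
})

test_that("log-rank is exchangeable and label-swap invariant", {
  time <- c(3, 5, 8, 3, 5, 8)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  grp <- rep(c("A", "B"), each = 3)
  got <- logrank_test(time, event, grp)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p.value, 1)
  swapped <- logrank_test(time, event, rev(grp))
  expect_equal(swapped$statistic, got$statistic, tolerance = 1e-12)
  expect_error(logrank_test(1:3, c(TRUE, TRUE, TRUE), c("A", "A", "A")),
               "two non-empty groups")
  expect_warning(out <- logrank_test(1:4, rep(FALSE, 4), rep(c("A", "B"), 2)),
                 "zero events")
  expect_null(out)
})

test_that("log-rank p-values are near-uniform under label permutation", {
  set.seed(77)
  n <- 40
  time <- rexp(n, 1 / 500)
  event <- runif(n) < 0.8
  ps <- vapply(1:400, function(i) {
    g <- sample(rep(c("A", "B"), n / 2))
    logrank_test(time, event, g)$p.value
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("BH adjustment reproduces hand-evaluated cases and the formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  set.seed(55)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))  # monotone along ranked p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cox beta matches direct partial-likelihood maximization", {
  # 4 patients, distinct times, binary covariate
  time <- c(2, 5, 11, 20)
  event <- c(TRUE, TRUE, TRUE, FALSE)
  x <- c(1, 0, 1, 0)
  got <- cox_univariate(time, event, x)
  beta_orc <- oracle_cox_beta(time, event, x)
  expect_equal(got$estimate, beta_orc, tolerance = 1e-6)
  expect_equal(got$hazard_ratio, exp(beta_orc), tolerance = 1e-5)

  # a second, larger no-ties case
  set.seed(66)
  n <- 30
  x2 <- rep(c(0, 1), 15)
  t2 <- rexp(n, exp(0.8 * x2) / 300)
  t2 <- t2 + seq_len(n) * 1e-6              # force distinct times
  e2 <- rep(TRUE, n)
  got2 <- cox_univariate(t2, e2, x2)
  expect_equal(got2$estimate, oracle_cox_beta(t2, e2, x2), tolerance = 1e-6)
})

test_that("flipping the group indicator inverts the hazard ratio", {
  set.seed(88)
  n <- 80
  x <- rep(c(0, 1), n / 2)
  time <- rexp(n, exp(0.7 * x) / 400)
  event <- runif(n) < 0.85
  a <- cox_univariate(time, event, x)
  b <- cox_univariate(time, event, 1 - x)
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-9)
  expect_equal(a$p.value, b$p.value, tolerance = 1e-9)
  expect_equal(a$hazard_ratio, 1 / b$hazard_ratio, tolerance = 1e-9)
})

test_that("a covariate independent of survival recovers HR near 1", {
  set.seed(99)
  n <- 600
  x <- rep(c(0, 1), n / 2)
  time <- rexp(n, 1 / 500)
  event <- runif(n) < 0.8
  got <- cox_univariate(time, event, x)
  expect_lt(abs(got$estimate), 0.25)
  expect_gt(got$p.value, 0.01)
})

test_that("complete separation is flagged as an infinite hazard ratio", {
  # all events in one group, far earlier than any other-group time
  time <- c(1, 2, 3, 100, 110, 120)
  event <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(got <- cox_univariate(time, event, x), "infinite")
  expect_true(got$hr_infinite)
  expect_true(is.infinite(got$hazard_ratio))
})

test_that("pair ranking preserves the cohort partition and finds the planted pair", {
  ch <- make_benchmark_cohort("small", seed = 5)
  surv <- suppressMessages(derive_survival(ch$clinical))
  gr <- split_cohort(ch$clinical)
  d <- suppressMessages(build_delta_matrix(ch$reference, ch$tumor[, gr$mut_ids],
                                           group_label = "mTP53"))
  sel <- suppressWarnings(average_delta_filter(d, select_pairs(d)))
  rk <- rank_pairs(d, surv, pairs = sel)
  expect_gt(nrow(rk), 0)
  # partition conservation for every reported pair
  expect_true(all(rk$n_large + rk$n_small == attr(rk, "n_cohort")))
  expect_true(all(rk$n_large >= 5 & rk$n_small >= 5))
  # output sorted by hazard ratio descending
  expect_true(all(diff(rk$hazard_ratio) <= 1e-12))
  # planted prognostic pair has the best adjusted p
  expect_equal(rk$pair[which.min(rk$adj_p)], "G001_G002")
  g <- glance(rk)
  expect_equal(g$n_pairs_tested, nrow(rk))
})

test_that("Kaplan-Meier coordinates are valid step functions per cluster", {
  ch <- make_benchmark_cohort("small", seed = 5)
  surv <- suppressMessages(derive_survival(ch$clinical))
  km <- km_curves(surv, large_ids = surv$sample_id[1:20],
                  small_ids = surv$sample_id[21:60])
  expect_setequal(unique(km$cluster), c("Large", "Small"))
  for (cl in c("Large", "Small")) {
    s <- km[km$cluster == cl, ]
    expect_true(all(diff(s$time) > 0))
    expect_true(all(diff(s$surv) <= 1e-12))   # survival never increases
    expect_true(all(s$surv >= 0 & s$surv <= 1))
  }
})

test_that("subsampling with fraction 1 reproduces the full-cohort result", {
  ch <- make_benchmark_cohort("small", seed = 5)
  surv <- suppressMessages(derive_survival(ch$clinical))
  gr <- split_cohort(ch$clinical)
  d <- suppressMessages(build_delta_matrix(ch$reference, ch$tumor[, gr$mut_ids]))
  sel <- suppressWarnings(average_delta_filter(d, select_pairs(d)))
  full <- rank_pairs(d, surv, pairs = sel)
  top <- full$pair[full$adj_p < 0.05]
  rep1 <- robustness_subsample(d, surv, pairs = sel, fraction = 1, repeats = 2, seed = 1)
  expect_equal(rep1$n_logrank_significant, rep(2L, length(top)))

  # determinism: same seed, same report
  a <- robustness_subsample(d, surv, pairs = sel, fraction = 0.9, repeats = 3, seed = 42)
  b <- robustness_subsample(d, surv, pairs = sel, fraction = 0.9, repeats = 3, seed = 42)
  expect_identical(a, b)
  # strongly planted pair stays significant in every repeat
  planted <- a[a$pair == "G001_G002", ]
  expect_equal(planted$n_logrank_significant, 3L)
})
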