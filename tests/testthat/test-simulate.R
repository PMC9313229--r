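test_that("expression simulation reproduces the configured correlation blocks", {
  cfg <- simulation_config(n_genes = 6, n_reference = 500, n_wt = 2, n_mut = 2,
                           correlation_blocks = list(list(genes = 1:3, r = 0.8)),
                           seed = 71)
  sim <- simulate_expression(cfg)
  emp <- cor(t(sim$reference[1:3, ]))
  # Fisher-z sampling error at n = 500 keeps |r_hat - 0.8| within ~0.06
  off <- abs(emp[upper.tri(emp)] - 0.8)
  expect_true(all(off < 0.06))
  # unblocked genes stay near independent
  emp2 <- cor(sim$reference["G004", ], sim$reference["G005", ])
  expect_lt(abs(emp2), 0.15)
})

test_that("simulation is bit-identical under the same seed and differs across seeds", {
  cfg <- simulation_config(n_genes = 10, n_reference = 20, n_wt = 5, n_mut = 5,
                           correlation_blocks = list(list(genes = 1:4, r = 0.9)),
                           planted_pairs = list(list(pair = "G001_G002",
                                                     magnitude = 0.7, group = "mut")),
                           seed = 5)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$mut, b$mut)
  cfg2 <- simulation_config(n_genes = 10, n_reference = 20, n_wt = 5, n_mut = 5,
                            correlation_blocks = list(list(genes = 1:4, r = 0.9)),
                            seed = 6)
  expect_false(identical(simulate_expression(cfg2)$reference, a$reference))
})

test_that("a non-positive-definite correlation request fails before sampling", {
  # negative equicorrelation beyond -1/(k-1) is not a correlation matrix
  expect_error(simulation_config(n_genes = 5, n_wt = 5, n_mut = 5,
                                 correlation_blocks = list(list(genes = 1:4, r = -0.5)),
                                 seed = 1),
               "positive definite")
})

test_that("survival simulation respects strata, horizon, and field conventions", {
  cfg <- simulation_config(n_genes = 4, n_reference = 10, n_wt = 5, n_mut = 5,
                           baseline_hazard = 1 / 500,
                           censoring_horizon_days = 2000, dropout_rate = 0.1,
                           seed = 31)
  strata <- setNames(rep(c("high", "low"), 50), sprintf("P%03d", 1:100))
  clin <- simulate_survival(strata, cfg, multiplier = 4, tp53_status = "mutated")
  expect_equal(nrow(clin), 100)
  expect_true(all(clin$vital_status %in% c("alive", "dead")))
  dead <- clin$vital_status == "dead"
  expect_true(all(!is.na(clin$days_to_death[dead])))
  expect_true(all(is.na(clin$days_to_death[!dead])))
  expect_true(all(stats::na.omit(c(clin$days_to_death, clin$days_to_last_follow_up)) <= 2000))
  # high stratum dies faster on average
  s <- suppressMessages(derive_survival(clin))
  hi <- s$sample_id %in% names(strata)[strata == "high"]
  expect_lt(median(s$time_days[hi]), median(s$time_days[!hi]))
  expect_error(simulate_survival(strata, cfg, multiplier = 0), "> 0")
})

test_that("a zero horizon censors everyone immediately and drops downstream", {
  cfg <- simulation_config(n_genes = 4, n_reference = 10, n_wt = 5, n_mut = 5,
                           censoring_horizon_days = 0, seed = 32)
  clin <- simulate_survival(setNames(rep("low", 10), paste0("P", 1:10)), cfg,
                            multiplier = 1)
  expect_true(all(clin$vital_status == "alive"))
  s <- suppressMessages(derive_survival(clin))
  expect_equal(nrow(s), 0)
})

test_that("a unit multiplier produces exchangeable strata", {
  ps <- vapply(1:25, function(i) {
    cfg <- simulation_config(n_genes = 4, n_reference = 10, n_wt = 5, n_mut = 5,
                             baseline_hazard = 1 / 800, seed = 1000 + i)
    strata <- setNames(rep(c("high", "low"), 30), sprintf("P%03d", 1:60))
    clin <- simulate_survival(strata, cfg, multiplier = 1)
    s <- suppressMessages(derive_survival(clin))
    grp <- s$sample_id %in% names(strata)[strata == "high"]
    logrank_test(s$time_days, s$event, grp)$p.value
  }, numeric(1))
  # p-values behave like a uniform draw, not like a signal
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("Cox recovers a planted hazard multiplier of 5", {
  # a single 95% CI misses the truth ~5% of the time by construction, so
  # the recovery check is coverage across seeds
  strata <- setNames(rep(c("high", "low"), 125), sprintf("P%03d", 1:250))
  covered <- 0
  for (i in 1:10) {
    cfg <- simulation_config(n_genes = 4, n_reference = 10, n_wt = 5, n_mut = 5,
                             baseline_hazard = 1 / 2000,
                             censoring_horizon_days = 10000, dropout_rate = 0.1,
                             seed = 70 + i)
    clin <- simulate_survival(strata, cfg, multiplier = 5)
    s <- suppressMessages(derive_survival(clin))
    x <- as.numeric(s$sample_id %in% names(strata)[strata == "high"])
    fit <- cox_univariate(s$time_days, s$event, x)
    ci <- exp(fit$estimate + c(-1.96, 1.96) * fit$std_error)
    if (ci[1] < 5 && 5 < ci[2]) covered <- covered + 1
  }
  expect_gte(covered, 8)
})

test_that("benchmark cohorts carry complete truth and are reproducible", {
  a <- make_benchmark_cohort("small", seed = 4)
  b <- make_benchmark_cohort("small", seed = 4)
  expect_identical(a$tumor, b$tumor)
  expect_identical(a$clinical, b$clinical)
  expect_equal(nrow(a$truth$planted_pairs), 3)
  expect_setequal(a$truth$planted_pairs$pair, c("G001_G002", "G003_G004", "G009_G010"))
  # affected ids exist in the right group
  gr <- split_cohort(a$clinical)
  for (i in seq_len(nrow(a$truth$planted_pairs))) {
    ids <- a$truth$planted_pairs$affected_ids[[i]]
    pool <- if (a$truth$planted_pairs$group[i] == "wt") gr$wt_ids else gr$mut_ids
    expect_true(all(ids %in% pool))
  }
  # the prognostic stratum is the planted pair's affected set
  expect_identical(a$truth$planted_prognostic$high_ids[[1]],
                   a$truth$planted_pairs$affected_ids[[1]])
  # two presets with one seed draw from disjoint substreams
  p <- make_benchmark_cohort("paper_shaped", seed = 4)
  expect_false(identical(p$reference[1:5, 1:5], a$reference[1:5, 1:5]))
  expect_equal(p$config$n_wt, 124)
  expect_equal(p$config$n_mut, 65)
})

test_that("cohort artifacts round-trip through the data-io readers", {
  ch <- make_benchmark_cohort("small", seed = 8)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_identical(expr, ch$tumor)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$sample_id, ch$clinical$sample_id)
  genes <- read_gene_list(file.path(dir, "genes.txt"))
  expect_identical(genes, rownames(ch$tumor))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(truth$planted_pairs$pair, ch$truth$planted_pairs$pair)
})
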