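test_that("pearson matches the defining sums on random vectors", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- cor_test(x, y)
    expect_equal(got$estimate, oracle_pearson(x, y), tolerance = 1e-12)
    expect_equal(got$p.value, oracle_cor_p(got$estimate, n), tolerance = 1e-12)
  }
})

test_that("perfect linear relations give |r| = 1 with p = 0", {
  up <- cor_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(up$estimate, 1)
  expect_equal(up$p.value, 0)
  down <- cor_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(down$estimate, -1)
})

test_that("the hand-computed 4-point example evaluates exactly", {
  # centered cross-product sum is 4.0 over sqrt(5 * 5): r = 0.8 exactly
  got <- cor_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$estimate, 0.8)
  expect_equal(got$p.value, 2 * pt(-0.8 * sqrt(2 / (1 - 0.64)), df = 2),
               tolerance = 1e-12)
})

test_that("zero-variance input is rejected", {
  expect_error(cor_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(cor_test(1:2, 2:3), "at least 3")
})

test_that("spearman is rank-invariant and handles ties by average ranks", {
  x <- c(0.3, 1.1, 2.2, 5.0, 9.7)
  expect_equal(cor_test(x, exp(x), method = "spearman")$estimate, 1)
  expect_equal(cor_test(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman")$estimate, 0.8)
  set.seed(202)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    y <- sample(round(rnorm(n), 1), n)   # rounded -> ties likely
    expect_equal(cor_test(x, y, method = "spearman")$estimate,
                 oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("Fisher z comparison matches the closed form and is symmetric", {
  expect_equal(compare_correlations(0.4, 50, 0.4, 200), 1)
  z <- (atanh(0.5) - atanh(0.3)) / sqrt(1 / 97 + 1 / 98)
  expect_equal(compare_correlations(0.5, 100, 0.3, 101), 2 * pnorm(-abs(z)),
               tolerance = 1e-12)
  expect_equal(compare_correlations(0.5, 100, 0.3, 101),
               compare_correlations(0.3, 101, 0.5, 100))
  expect_equal(compare_correlations(0.5, 100, 0.3, 101),
               oracle_fisher_z(0.5, 100, 0.3, 101), tolerance = 1e-12)
  expect_error(compare_correlations(1, 10, 0.5, 10), "infinite")
  expect_error(compare_correlations(0.5, 3, 0.5, 10), "n >= 4")
})

test_that("Fisher z p-value decreases in the transformed gap at fixed n", {
  gaps <- seq(0.05, 1, by = 0.05)
  ps <- vapply(gaps, function(g) compare_correlations(tanh(0.5 + g), 40, tanh(0.5), 40),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("delta_pcc equals brute-force recomputation on the augmented panel", {
  set.seed(303)
  for (i in 1:20) {
    ref <- fixture_expression(g = 2, s = 5, seed = 300 + i)
    rownames(ref) <- c("GA", "GB")
    patient <- c(GA = rnorm(1, 8), GB = rnorm(1, 8))
    got <- delta_pcc(ref, patient, "GA", "GB")
    r_n <- oracle_pearson(ref["GA", ], ref["GB", ])
    r_n1 <- oracle_pearson(c(ref["GA", ], patient["GA"]), c(ref["GB", ], patient["GB"]))
    expect_equal(got, abs(r_n1 - r_n), tolerance = 1e-12)
  }
})

test_that("a patient at the reference mean leaves the correlation unchanged", {
  ref <- fixture_expression(g = 2, s = 10, seed = 7)
  rownames(ref) <- c("GA", "GB")
  patient <- c(GA = mean(ref["GA", ]), GB = mean(ref["GB", ]))
  expect_equal(delta_pcc(ref, patient, "GA", "GB"), 0, tolerance = 1e-12)
})

test_that("delta_pcc is invariant to reference column order and gene swap", {
  ref <- fixture_expression(g = 2, s = 8, seed = 17)
  rownames(ref) <- c("GA", "GB")
  patient <- c(GA = 9.4, GB = 6.1)
  base <- delta_pcc(ref, patient, "GA", "GB")
  set.seed(1)
  shuf <- ref[, sample(ncol(ref))]
  expect_equal(delta_pcc(shuf, patient, "GA", "GB"), base, tolerance = 1e-14)
  expect_equal(delta_pcc(ref, patient, "GB", "GA"), base, tolerance = 1e-14)
})

test_that("delta matrix has one bounded entry per patient-pair combination", {
  ref <- fixture_expression(g = 4, s = 10, seed = 21)
  pats <- fixture_expression(g = 4, s = 3, seed = 22)
  colnames(pats) <- c("P1", "P2", "P3")
  d <- build_delta_matrix(ref, pats)
  expect_equal(dim(d$delta), c(3, choose(4, 2)))
  expect_true(all(d$delta >= 0 & d$delta <= 2))
  expect_equal(d$reference_n, 10)
  # base case: single patient, single pair equals the scalar op
  d1 <- build_delta_matrix(ref, pats[, 1, drop = FALSE],
                           pairs = gene_pairs("G001", "G002"))
  expect_equal(unname(d1$delta[1, 1]),
               delta_pcc(ref, pats[, 1], "G001", "G002"), tolerance = 1e-14)
  # long view covers every combination once
  expect_equal(nrow(tidy(d)), 3 * choose(4, 2))
})

test_that("selection criteria gate in order and pass a planted perturbation", {
  set.seed(42)
  # reference: two strongly correlated genes + two independent ones
  n <- 60
  z <- rnorm(n)
  ref <- rbind(GA = 8 + z + 0.3 * rnorm(n),
               GB = 8 + z + 0.3 * rnorm(n),
               GC = 8 + rnorm(n),
               GD = 8 + rnorm(n))
  colnames(ref) <- sprintf("R%02d", 1:n)
  # one conforming patient and one discordant high-leverage patient
  pats <- cbind(conform = c(GA = 8, GB = 8, GC = 8, GD = 8),
                perturb = c(GA = 12, GB = 4, GC = 8, GD = 8))
  d <- build_delta_matrix(ref, pats)
  sel <- suppressWarnings(select_pairs(d, alpha = 0.05))

  ga_gb <- sel[sel$pair == "GA_GB", ]
  expect_true(ga_gb$retained)
  expect_gte(ga_gb$n_patients_pass, 1)
  # uncorrelated pair dies at criterion 1 regardless of patients
  gc_gd <- sel[sel$pair == "GC_GD", ]
  expect_false(gc_gd$retained)
  expect_equal(gc_gd$fail_reason, "reference_pcc_not_significant")
  # direct criterion evaluation for the perturbing patient
  r_ref <- cor(ref["GA", ], ref["GB", ])
  r_aug <- cor(c(ref["GA", ], 12), c(ref["GB", ], 4))
  expect_lt(oracle_cor_p(r_ref, n), 0.05)
  expect_lt(oracle_cor_p(r_aug, n + 1), 0.05)
  expect_lt(oracle_fisher_z(r_ref, n, r_aug, n + 1), 0.05)
})

test_that("alpha = 1 retains every pair with defined correlations", {
  ref <- fixture_expression(g = 4, s = 12, seed = 31)
  pats <- fixture_expression(g = 4, s = 4, seed = 32)
  colnames(pats) <- paste0("P", 1:4)
  d <- build_delta_matrix(ref, pats)
  sel <- select_pairs(d, alpha = 1)
  expect_true(all(sel$retained))
})

test_that("average-delta filter keeps pairs above the grand mean, strictly", {
  ref <- fixture_expression(g = 4, s = 12, seed = 51)
  pats <- fixture_expression(g = 4, s = 6, seed = 52)
  colnames(pats) <- paste0("P", 1:6)
  d <- build_delta_matrix(ref, pats)
  sel <- select_pairs(d, alpha = 1)          # keep everything defined
  filt <- average_delta_filter(d, sel)
  grand <- mean(d$delta)
  expect_equal(attr(filt, "grand_mean_delta"), grand)
  # brute-force recomputation of the retained set
  manual <- colMeans(d$delta) > grand
  expect_equal(setNames(filt$retained, filt$pair), manual[filt$pair])
  expect_true(all(filt$fail_reason[!filt$retained] == "below_average_delta_pcc"))

  # identical per-pair means equal the grand mean -> all rejected
  d2 <- d
  d2$delta[] <- 0.25
  filt2 <- average_delta_filter(d2, sel)
  expect_false(any(filt2$retained))
})
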