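# deterministic substream seeds: one master seed, named offsets per random
# component, everything kept below 2^31 - 1
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647)
}
.substreams <- c(expression = 1, perturbation = 2, survival = 3, dropout = 4,
                 affected = 5)

#' Configuration of a synthetic two-group cohort
#'
#' Defines the study conditions emulated by the generator: a normal
#' reference panel with block-structured gene-gene correlation, two tumor
#' groups (wild-type / mutated TP53 analogues) in which selected gene
#' pairs are perturbed in a subset of patients, and right-censored
#' overall-survival times whose hazard depends on membership in a planted
#' pair's perturbed stratum.
#'
#' @param n_genes Number of genes (named `G001`, `G002`, ...).
#' @param n_reference Normal reference panel size (default 100, the panel
#'   size the selection criteria are calibrated for).
#' @param n_wt,n_mut Tumor group sizes.
#' @param correlation_blocks List of `list(genes =, r =)`: gene indices and
#'   the within-block correlation in (-1, 1). Unlisted genes are
#'   independent. The implied correlation matrix must be positive definite.
#' @param planted_pairs List of `list(pair =, magnitude =, group =)`:
#'   pair label, perturbation magnitude (target drop in the pair's
#'   correlation), and affected group (`"wt"` or `"mut"`). In
#'   `affected_fraction` of that group's patients the pair's two values
#'   are replaced by a discordant high-leverage point — a displacement
#'   against the pair's correlation structure whose radius is calibrated,
#'   from the configured block correlation and the reference panel size,
#'   so a single affected sample moves the panel correlation by about
#'   `magnitude` (capped at the significance floor: the perturbed
#'   correlation is kept just inside detectability, since a sample that
#'   annihilates the correlation outright leaves nothing to test).
#' @param planted_prognostic List of `list(pair =, multiplier =)`: hazard
#'   multiplier applied to the perturbed (high delta-PCC) stratum of that
#'   planted pair's group.
#' @param affected_fraction Fraction of the group's patients perturbed per
#'   planted pair (default 0.3).
#' @param perturb_jitter Relative jitter on the planted leverage points
#'   (default 0.15), so affected patients scatter around the calibrated
#'   displacement instead of coinciding.
#' @param baseline_hazard Baseline event rate per day (default 5e-4,
#'   median overall survival about 3.8 years).
#' @param censoring_horizon_days Administrative censoring horizon (default
#'   3650 days).
#' @param dropout_rate Probability of uniform early dropout (default 0.2).
#' @param noise_sd Marginal expression SD (default 1) around a baseline
#'   mean of 8 on the log2-like scale.
#' @param seed Master integer seed (mandatory); all random components use
#'   named substreams derived from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes, n_reference = 100, n_wt, n_mut,
                              correlation_blocks = list(),
                              planted_pairs = list(),
                              planted_prognostic = list(),
                              affected_fraction = 0.3, perturb_jitter = 0.15,
                              baseline_hazard = 5e-4,
                              censoring_horizon_days = 3650,
                              dropout_rate = 0.2, noise_sd = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  stopifnot(n_genes >= 2, n_reference >= 3, n_wt >= 2, n_mut >= 2,
            affected_fraction > 0, affected_fraction <= 1,
            perturb_jitter >= 0, baseline_hazard > 0,
            censoring_horizon_days >= 0, dropout_rate >= 0, dropout_rate <= 1,
            noise_sd > 0)
  cfg <- list(n_genes = n_genes, n_reference = n_reference, n_wt = n_wt,
              n_mut = n_mut, correlation_blocks = correlation_blocks,
              planted_pairs = planted_pairs,
              planted_prognostic = planted_prognostic,
              affected_fraction = affected_fraction,
              perturb_jitter = perturb_jitter, baseline_hazard = baseline_hazard,
              censoring_horizon_days = censoring_horizon_days,
              dropout_rate = dropout_rate, noise_sd = noise_sd,
              baseline_mean = 8, seed = as.integer(seed))
  # fail on a non-PD request before any sampling
  invisible(correlation_matrix(cfg))
  for (pp in cfg$planted_pairs) {
    stopifnot(!is.null(pp$pair), !is.null(pp$magnitude), pp$group %in% c("wt", "mut"))
  }
  for (pg in cfg$planted_prognostic) {
    if (is.null(pg$multiplier) || pg$multiplier <= 0) {
      abort("planted prognostic hazard multiplier must be > 0")
    }
    if (!pg$pair %in% vapply(cfg$planted_pairs, `[[`, "", "pair")) {
      abort(sprintf("planted prognostic pair %s is not among the planted pairs", pg$pair))
    }
  }
  structure(cfg, class = "simulation_config")
}

gene_names <- function(n) sprintf("G%03d", seq_len(n))

correlation_matrix <- function(config) {
  g <- config$n_genes
  S <- diag(g)
  for (bl in config$correlation_blocks) {
    idx <- bl$genes
    stopifnot(all(idx >= 1 & idx <= g), abs(bl$r) < 1)
    S[idx, idx] <- bl$r
    diag(S)[idx] <- 1
  }
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) abort("requested correlation structure is not positive definite")
  attr(S, "chol") <- ch
  S
}

mvn_draw <- function(n, chol_S) {
  g <- ncol(chol_S)
  matrix(rnorm(n * g), n, g) %*% chol_S
}

pair_index <- function(pair_label, genes) {
  parts <- stringr::str_split_fixed(pair_label, "_", 2)
  idx <- match(c(parts[1], parts[2]), genes)
  if (anyNA(idx)) abort(sprintf("planted pair %s not in gene universe", pair_label))
  idx
}

# correlation significance threshold: smallest |r| with two-sided p < alpha
# at sample size n (from the exact t transform)
r_significance_floor <- function(n, alpha = 0.05) {
  t_crit <- stats::qt(1 - alpha / 2, df = n - 2)
  t_crit / sqrt(n - 2 + t_crit^2)
}

# leverage radius (in marginal SDs) placing one discordant sample so the
# augmented panel correlation lands near r_target: adding the centered
# point (s, -s) to n-1 standardized sums gives
#   r_aug ~ ((n-1) r0 - s^2) / ((n-1) + s^2)
planted_leverage <- function(r0, r_target, n) {
  sqrt((n - 1) * (r0 - r_target) / (1 + r_target))
}

#' Simulate reference and tumor expression with planted perturbed pairs
#'
#' Draws the reference panel and both tumor groups from a multivariate
#' normal with the configured block correlation structure. For each
#' planted pair, a random subset (`affected_fraction`) of the affected
#' group's patients has that pair's two values replaced by a discordant
#' leverage point: a displacement against the pair's co-expression
#' direction whose radius is calibrated so that adding that one sample to
#' the reference panel moves the pair's correlation by about the planted
#' magnitude — capped so the perturbed correlation stays just inside the
#' significance floor, because the selection criteria require the
#' augmented correlation to remain significant while differing
#' significantly from the panel's. This is the single-sample signal the
#' selection criteria are built to detect.
#'
#' @param config A `simulation_config`.
#' @return A list: `reference`, `wt`, `mut` (genes-by-samples matrices),
#'   and `truth` — a tibble per planted pair with its affected sample ids.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  S <- correlation_matrix(config)
  ch <- attr(S, "chol")
  genes <- gene_names(config$n_genes)
  mu <- config$baseline_mean; sdv <- config$noise_sd

  set.seed(substream_seed(config$seed, .substreams[["expression"]]))
  reference <- t(mu + sdv * mvn_draw(config$n_reference, ch))
  wt <- t(mu + sdv * mvn_draw(config$n_wt, ch))
  mut <- t(mu + sdv * mvn_draw(config$n_mut, ch))
  rownames(reference) <- rownames(wt) <- rownames(mut) <- genes
  colnames(reference) <- sprintf("REF%03d", seq_len(config$n_reference))
  colnames(wt) <- sprintf("WT%03d", seq_len(config$n_wt))
  colnames(mut) <- sprintf("MUT%03d", seq_len(config$n_mut))

  truth <- tibble(pair = character(), magnitude = double(), group = character(),
                  affected_ids = list())
  set.seed(substream_seed(config$seed, .substreams[["affected"]]))
  affected_sets <- lapply(config$planted_pairs, function(pp) {
    grp <- if (pp$group == "wt") wt else mut
    sort(sample(colnames(grp), ceiling(config$affected_fraction * ncol(grp))))
  })
  set.seed(substream_seed(config$seed, .substreams[["perturbation"]]))
  n_ref <- config$n_reference
  for (k in seq_along(config$planted_pairs)) {
    pp <- config$planted_pairs[[k]]
    idx <- pair_index(pp$pair, genes)
    # calibrate against the realized panel correlation: the planted sample
    # perturbs the panel that was actually drawn, not the population value
    r0 <- cor(reference[idx[1], ], reference[idx[2], ])
    sgn0 <- sign(r0 + (r0 == 0))
    # detection band for the augmented correlation, in atanh space:
    # criterion 2 needs it significant (>= lo), criterion 3 needs it
    # significantly below the panel's (<= hi)
    lo <- atanh(r_significance_floor(n_ref + 1))
    hi <- abs(atanh(r0)) -
      stats::qnorm(0.975) * sqrt(1 / (n_ref - 3) + 1 / (n_ref - 2))
    naive <- abs(atanh(max(min(abs(r0) - pp$magnitude, 0.99), 0)))
    target_at <- if (hi <= lo) {
      warn(sprintf(
        "planted pair %s: panel correlation %.2f too weak for single-sample detection at panel size %d",
        pp$pair, r0, n_ref))
      lo
    } else if (naive < lo) lo + 0.25 * (hi - lo) else min(naive, hi)
    r_target <- tanh(target_at) * sgn0
    s <- planted_leverage(abs(r0), abs(r_target), n_ref)
    aff <- affected_sets[[k]]
    n_aff <- length(aff)
    sgn <- sample(c(-1, 1), n_aff, replace = TRUE)
    jit <- config$perturb_jitter
    a <- sgn * s * (1 + jit * rnorm(n_aff))
    b <- -sgn0 * sgn * s * (1 + jit * rnorm(n_aff))
    draw <- rbind(mu + sdv * a, mu + sdv * b)
    if (pp$group == "wt") wt[idx, aff] <- draw else mut[idx, aff] <- draw
    truth <- bind_rows(truth, tibble(pair = pp$pair, magnitude = pp$magnitude,
                                     group = pp$group, affected_ids = list(aff)))
  }
  list(reference = reference, wt = wt, mut = mut, truth = truth)
}

#' Simulate right-censored overall survival for one patient group
#'
#' Event times are exponential with hazard
#' `baseline_hazard * multiplier^(stratum == "high")`; censoring is
#' administrative at the horizon, with a `dropout_rate` chance of uniform
#' early dropout. Outputs the clinical fields the data-io module reads
#' (`days_to_death`, `days_to_last_follow_up`, `vital_status`).
#'
#' @param strata Named character vector (`"high"` / `"low"`) per sample
#'   id, or a tibble with columns `sample_id`, `stratum`.
#' @param config A `simulation_config` (hazard, horizon, dropout, seed).
#' @param multiplier Hazard multiplier for the high stratum (> 0; default
#'   taken from the first `planted_prognostic` entry, else 1).
#' @param tp53_status Group label written into the table (`"wild_type"` or
#'   `"mutated"`).
#' @param stream_offset Extra offset added to the survival substream so
#'   the two groups draw disjoint streams.
#' @return A clinical tibble (one row per sample).
#' @export
simulate_survival <- function(strata, config, multiplier = NULL,
                              tp53_status = "wild_type", stream_offset = 0) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.data.frame(strata)) strata <- setNames(strata$stratum, strata$sample_id)
  if (is.null(multiplier)) {
    multiplier <- if (length(config$planted_prognostic) > 0)
      config$planted_prognostic[[1]]$multiplier else 1
  }
  if (multiplier <= 0) abort("hazard multiplier must be > 0")
  stopifnot(all(strata %in% c("high", "low")))
  n <- length(strata)
  haz <- config$baseline_hazard * ifelse(strata == "high", multiplier, 1)

  set.seed(substream_seed(config$seed, .substreams[["survival"]] + stream_offset))
  t_event <- rexp(n, rate = haz)
  set.seed(substream_seed(config$seed, .substreams[["dropout"]] + stream_offset))
  horizon <- config$censoring_horizon_days
  dropout <- runif(n) < config$dropout_rate
  censor <- ifelse(dropout, runif(n, 0, horizon), horizon)
  event <- t_event <= censor
  days <- as.integer(ceiling(pmin(t_event, censor)))

  tibble(
    sample_id = names(strata),
    days_to_death = ifelse(event, days, NA_integer_),
    days_to_last_follow_up = ifelse(event, NA_integer_, days),
    vital_status = ifelse(event, "dead", "alive"),
    tp53_status = tp53_status,
    subtype = NA_character_
  )
}

#' Generate a ready-to-analyze benchmark cohort
#'
#' Two presets of the full synthetic study:
#' * `small` — 40 genes (three correlated blocks of 8 at r = 0.85 / 0.80 /
#'   0.75; the small panel raises the single-sample detection floor, so
#'   the blocks sit well above it), 50 reference samples, 60 + 60
#'   patients, three planted
#'   perturbed pairs (two in the mutated group, one in the wild-type
#'   group) of magnitude 0.7, and one planted prognostic pair
#'   (`G001_G002`, hazard multiplier 6 in its perturbed stratum). Runs
#'   through the whole pipeline in seconds.
#' * `paper_shaped` — the same design scaled to the shape of a real
#'   mutation-stratified cohort at one quarter scale: 129 genes (three
#'   blocks of 26), 100 reference samples, 124 wild-type + 65 mutated
#'   patients.
#'
#' The two presets draw from disjoint substream families of the same
#' master seed, so both are independently reproducible.
#'
#' @param preset `"small"` or `"paper_shaped"`.
#' @param seed Master integer seed (default 1).
#' @return A `synthetic_cohort`: `reference`, `tumor` (wt and mut columns
#'   combined), `clinical`, `truth` (planted pairs, their affected ids,
#'   and the prognostic stratum), and the `config`.
#' @export
make_benchmark_cohort <- function(preset = c("small", "paper_shaped"), seed = 1) {
  preset <- match.arg(preset)
  base <- if (preset == "small") 0 else 1000
  if (preset == "small") {
    cfg <- simulation_config(
      n_genes = 40, n_reference = 50, n_wt = 60, n_mut = 60,
      correlation_blocks = list(list(genes = 1:8, r = 0.85),
                                list(genes = 9:16, r = 0.80),
                                list(genes = 17:24, r = 0.75)),
      planted_pairs = list(
        list(pair = "G001_G002", magnitude = 0.7, group = "mut"),
        list(pair = "G003_G004", magnitude = 0.7, group = "mut"),
        list(pair = "G009_G010", magnitude = 0.7, group = "wt")),
      planted_prognostic = list(list(pair = "G001_G002", multiplier = 6)),
      seed = substream_seed(seed, base))
  } else {
    cfg <- simulation_config(
      n_genes = 129, n_reference = 100, n_wt = 124, n_mut = 65,
      correlation_blocks = list(list(genes = 1:26, r = 0.75),
                                list(genes = 27:52, r = 0.70),
                                list(genes = 53:78, r = 0.65)),
      planted_pairs = list(
        list(pair = "G001_G002", magnitude = 0.7, group = "mut"),
        list(pair = "G003_G004", magnitude = 0.7, group = "mut"),
        list(pair = "G027_G028", magnitude = 0.7, group = "wt")),
      planted_prognostic = list(list(pair = "G001_G002", multiplier = 6)),
      seed = substream_seed(seed, base))
  }
  sim <- simulate_expression(cfg)

  prog <- cfg$planted_prognostic[[1]]
  prog_truth <- sim$truth[sim$truth$pair == prog$pair, ]
  prog_group <- prog_truth$group[[1]]
  high_ids <- prog_truth$affected_ids[[1]]

  make_strata <- function(ids, grp) {
    setNames(ifelse(grp == prog_group & ids %in% high_ids, "high", "low"), ids)
  }
  clin_wt <- simulate_survival(make_strata(colnames(sim$wt), "wt"), cfg,
                               multiplier = prog$multiplier,
                               tp53_status = "wild_type", stream_offset = 0)
  clin_mut <- simulate_survival(make_strata(colnames(sim$mut), "mut"), cfg,
                                multiplier = prog$multiplier,
                                tp53_status = "mutated", stream_offset = 10)

  truth <- list(
    planted_pairs = sim$truth,
    planted_prognostic = tibble(pair = prog$pair, multiplier = prog$multiplier,
                                group = prog_group, high_ids = list(high_ids))
  )
  structure(list(
    reference = sim$reference,
    tumor = cbind(sim$wt, sim$mut),
    clinical = bind_rows(clin_wt, clin_mut),
    truth = truth, config = cfg, preset = preset
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort '%s'> %d genes; reference n = %d; wt n = %d; mut n = %d; %d planted pair(s)\n",
              x$preset, nrow(x$tumor), ncol(x$reference),
              x$config$n_wt, x$config$n_mut, nrow(x$truth$planted_pairs)))
  invisible(x)
}

#' Write a synthetic cohort to the artifact formats the pipeline reads
#'
#' Writes `expression.tsv` (tumor), `reference.tsv`, `clinical.tsv`,
#' `genes.txt`, `truth.json`, and `config.yaml` into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$tumor, file.path(dir, "expression.tsv"))
  write_expression(cohort$reference, file.path(dir, "reference.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"), na = "",
                   progress = FALSE)
  readr::write_lines(rownames(cohort$tumor), file.path(dir, "genes.txt"))
  jsonlite::write_json(list(
    planted_pairs = cohort$truth$planted_pairs,
    planted_prognostic = cohort$truth$planted_prognostic
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(cohort$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
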