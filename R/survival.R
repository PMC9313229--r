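# Exact Ward-criterion two-cluster partition of scalar values: the optimal
# 2-partition minimizing total within-cluster sum of squares is contiguous
# in sorted order, so a threshold scan over the n-1 cut points finds it.
# Ties between cut points resolve to the smallest cut (deterministic).
ward_split_1d <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); css <- cumsum(xs^2); tot <- cs[n]; tots <- css[n]
  k <- seq_len(n - 1)
  wss_left <- css[k] - cs[k]^2 / k
  wss_right <- (tots - css[k]) - (tot - cs[k])^2 / (n - k)
  wss <- wss_left + wss_right
  kbest <- which.min(wss)
  cluster <- integer(n)
  cluster[o[seq_len(kbest)]] <- 1L
  cluster[o[(kbest + 1):n]] <- 2L
  cluster
}

#' Stratify a patient group by a gene pair's delta-PCC values
#'
#' Partitions the group into two clusters on the one-dimensional delta-PCC
#' axis using the Ward criterion (minimum total within-cluster sum of
#' squares; the optimal two-cluster partition of scalar data, found
#' exactly by an exhaustive contiguous-threshold scan). The cluster with
#' the strictly greater mean delta-PCC is labeled `"Large"`. Sample ids are
#' sorted lexicographically before splitting so the result is independent
#' of input order, with ties on the value broken by id.
#'
#' @param delta_values Named numeric vector of delta-PCC values, names =
#'   sample ids (>= 2 patients; `NA` entries are dropped).
#' @param pair Optional pair label carried into the result.
#' @return A list with `pair`, `large_ids`, `small_ids` (disjoint,
#'   exhaustive), or `NULL` with a warning when all values are identical
#'   (no two-cluster structure exists).
#' @export
stratify_by_pair <- function(delta_values, pair = NULL) {
  v <- delta_values[!is.na(delta_values)]
  if (length(v) < 2) abort("need >= 2 patients with defined delta-PCC to stratify")
  if (is.null(names(v))) abort("`delta_values` must be named by sample id")
  v <- v[order(v, names(v))]
  if (diff(range(v)) == 0) {
    warn(sprintf("all delta-PCC values identical%s; stratification degenerate",
                 if (!is.null(pair)) paste0(" for pair ", pair) else ""))
    return(NULL)
  }
  cl <- ward_split_1d(v)
  m1 <- mean(v[cl == 1L]); m2 <- mean(v[cl == 2L])
  large <- if (m1 > m2) 1L else 2L
  list(pair = pair %||% NA_character_,
       large_ids = sort(names(v)[cl == large]),
       small_ids = sort(names(v)[cl != large]))
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square (1 df) on right-censored
#' survival, two-sided p-value.
#'
#' @param time Positive survival/censoring times.
#' @param event Logical event indicators (`TRUE` = death observed).
#' @param group Two-level grouping vector; both levels must be non-empty.
#' @return A one-row tibble with `statistic` (chi-square) and `p.value`,
#'   or an error/`NULL` for degenerate input: an empty group is an error,
#'   zero events returns `NULL` with a warning.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(droplevels(group)) != 2) {
    abort("log-rank test needs exactly two non-empty groups")
  }
  if (sum(event) == 0) {
    warn("log-rank test undefined with zero events")
    return(NULL)
  }
  fit <- survdiff(Surv(time, event) ~ group)
  tibble(statistic = fit$chisq,
         p.value = pchisq(fit$chisq, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with the p-values ranked `p_(1) <= ... <=
#' p_(m)`, the adjusted value is the running minimum (from the largest rank
#' down) of `min(1, p_(j) * m / j)`, mapped back to input order. The
#' running minimum enforces monotonicity of the adjusted sequence; the
#' plain `min(1, p * m / j)` map alone can invert it.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order, each `>=` its raw p-value.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` by partial-likelihood maximization with
#' the Efron approximation for tied event times (convergence tolerance
#' 1e-9, at most 100 iterations), and reports the hazard ratio
#' `exp(beta)`, the Wald p-value, and Harrell's concordance over comparable
#' pairs. A monotone likelihood (complete separation of the groups'
#' event experience) is flagged: the hazard ratio is set to `+Inf` (or 0)
#' and `hr_infinite = TRUE`, with a warning.
#'
#' @param time Positive survival/censoring times.
#' @param event Logical event indicators.
#' @param x Covariate: binary indicator (e.g. Large-cluster membership) or
#'   continuous (e.g. standardized expression). A binary `x` must have
#'   both levels present; at least one event is required.
#' @return A one-row tibble: `estimate` (beta), `hazard_ratio`,
#'   `std_error`, `p.value`, `concordance`, `hr_infinite`.
#' @export
cox_univariate <- function(time, event, x) {
  if (sum(event) == 0) abort("Cox model undefined with zero events")
  xv <- if (is.logical(x) || is.factor(x)) as.numeric(as.factor(x)) else as.numeric(x)
  if (length(unique(xv)) < 2) abort("covariate is constant; both levels must be present")
  sep <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ xv, ties = "efron",
          control = coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|ran out of iterations", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  conc <- unname(fit$concordance["concordance"])
  # monotone likelihood: coefficient diverges; |beta| beyond ~15 means the
  # finite value is an artifact of the iteration cap
  if (sep || abs(beta) > 15) {
    warn("monotone partial likelihood (complete separation); hazard ratio reported as infinite")
    hr <- if (beta > 0) Inf else 0
    return(tibble(estimate = beta, hazard_ratio = hr, std_error = se,
                  p.value = NA_real_, concordance = conc, hr_infinite = TRUE))
  }
  tibble(estimate = beta, hazard_ratio = exp(beta), std_error = se,
         p.value = 2 * pnorm(-abs(beta / se)),
         concordance = conc, hr_infinite = FALSE)
}

#' Rank gene pairs by prognostic power within one patient group
#'
#' For each retained pair: stratify the group's patients into Large/Small
#' delta-PCC clusters ([stratify_by_pair()]), compare the clusters'
#' survival by the log-rank test, and fit a univariate Cox model on the
#' Large-cluster indicator for the hazard ratio, Wald p-value, and
#' concordance. Log-rank p-values are BH-adjusted across all pairs tested
#' in the group (one family per group; groups analyzed separately are
#' separate families). Pairs whose smaller cluster falls below
#' `min_cluster` are excluded — survival tests on near-singleton clusters
#' are unstable — as are degenerate or zero-event pairs; exclusions are
#' recorded with reasons in the `skipped` attribute.
#'
#' @param delta A `delta_pcc` object for the group.
#' @param survival A survival tibble from [derive_survival()]; only
#'   patients present in both are analyzed.
#' @param pairs Character vector of pair labels to test, or a
#'   `pair_selection` (its retained pairs are used), or `NULL` for all
#'   pairs in `delta`.
#' @param min_cluster Minimum size of each cluster (default 5).
#' @return A `pair_survival` tibble sorted by hazard ratio descending:
#'   `pair`, `n_large`, `n_small`, `logrank_p`, `adj_p`, `hazard_ratio`,
#'   `cox_p`, `concordance`, `hr_infinite`, plus the Large/Small id sets
#'   in list-columns `large_ids`, `small_ids`.
#' @export
rank_pairs <- function(delta, survival, pairs = NULL, min_cluster = 5) {
  stopifnot(inherits(delta, "delta_pcc"), is.data.frame(survival))
  if (inherits(pairs, "pair_selection")) pairs <- pairs$pair[pairs$retained]
  if (is.null(pairs)) pairs <- colnames(delta$delta)
  missing <- setdiff(pairs, colnames(delta$delta))
  if (length(missing) > 0) {
    abort(paste0("pair(s) absent from delta matrix: ", paste(head(missing, 5), collapse = ", ")))
  }
  ids <- intersect(rownames(delta$delta), survival$sample_id)
  if (length(ids) < 2 * min_cluster) {
    abort("too few patients with both delta-PCC and survival data")
  }
  sv <- survival[match(ids, survival$sample_id), ]

  rows <- list(); skipped <- list()
  for (pr in pairs) {
    v <- delta$delta[ids, pr]
    if (sum(!is.na(v)) < 2 * min_cluster) {
      skipped[[pr]] <- "too_few_defined_deltas"; next
    }
    strat <- withCallingHandlers(stratify_by_pair(v, pair = pr),
                                 warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(strat)) { skipped[[pr]] <- "degenerate_deltas"; next }
    if (min(length(strat$large_ids), length(strat$small_ids)) < min_cluster) {
      skipped[[pr]] <- "cluster_below_minimum_size"; next
    }
    all_ids <- c(strat$large_ids, strat$small_ids)
    s <- sv[match(all_ids, sv$sample_id), ]
    grp <- all_ids %in% strat$large_ids
    if (sum(s$event) == 0) { skipped[[pr]] <- "zero_events"; next }
    lr <- suppressWarnings(logrank_test(s$time_days, s$event, grp))
    cx <- tryCatch(suppressWarnings(cox_univariate(s$time_days, s$event, grp)),
                   error = function(e) NULL)
    if (is.null(lr) || is.null(cx)) { skipped[[pr]] <- "model_failure"; next }
    rows[[pr]] <- tibble(
      pair = pr, n_large = length(strat$large_ids), n_small = length(strat$small_ids),
      logrank_p = lr$p.value, hazard_ratio = cx$hazard_ratio, cox_p = cx$p.value,
      concordance = cx$concordance, hr_infinite = cx$hr_infinite,
      large_ids = list(strat$large_ids), small_ids = list(strat$small_ids)
    )
  }
  out <- if (length(rows) > 0) list_rbind(unname(rows)) else
    tibble(pair = character(), n_large = integer(), n_small = integer(),
           logrank_p = double(), hazard_ratio = double(), cox_p = double(),
           concordance = double(), hr_infinite = logical(),
           large_ids = list(), small_ids = list())
  if (nrow(out) > 0) {
    out$adj_p <- bh_adjust(out$logrank_p)
    out <- out %>%
      select("pair", "n_large", "n_small", "logrank_p", "adj_p", everything()) %>%
      arrange(desc(.data$hazard_ratio), .data$pair)
  } else {
    out$adj_p <- double()
    out <- out %>% select("pair", "n_large", "n_small", "logrank_p", "adj_p", everything())
  }
  structure(out, skipped = tibble(pair = names(skipped),
                                  reason = unlist(skipped) %||% character()),
            n_cohort = length(ids), min_cluster = min_cluster,
            class = c("pair_survival", class(out)))
}

#' @export
glance.pair_survival <- function(x, ...) {
  tibble(n_pairs_tested = nrow(x),
         n_pairs_skipped = nrow(attr(x, "skipped")),
         n_cohort = attr(x, "n_cohort"),
         n_bh_significant = sum(x$adj_p < 0.05),
         min_cluster = attr(x, "min_cluster"))
}

#' Stability of top pairs under patient subsampling
#'
#' Re-runs the per-pair survival ranking on random subsamples of the group
#' (default: 90% of patients, three repeats) and reports, for each pair of
#' interest, in how many repeats it remained significant under two
#' screens: (a) BH-adjusted log-rank p < 0.05 and (b) Cox Wald p < 1e-4.
#'
#' @param delta A `delta_pcc` object for the group.
#' @param survival A survival tibble from [derive_survival()].
#' @param pairs Pairs to test on each subsample (labels or a
#'   `pair_selection`), as in [rank_pairs()].
#' @param top_pairs Pair labels whose stability is reported; default =
#'   pairs BH-significant at 0.05 in the full-cohort ranking.
#' @param fraction Fraction of patients kept per repeat (default 0.9).
#' @param repeats Number of subsample repeats (default 3).
#' @param seed Integer seed; repeat `r` uses the deterministic substream
#'   `seed + r`.
#' @param min_cluster Passed to [rank_pairs()].
#' @return A tibble with one row per reported pair: `pair`, `repeats`,
#'   `n_logrank_significant`, `n_cox_significant`, and the full-cohort
#'   `adj_p`/`cox_p` for reference.
#' @export
robustness_subsample <- function(delta, survival, pairs = NULL, top_pairs = NULL,
                                 fraction = 0.9, repeats = 3, seed = 1,
                                 min_cluster = 5) {
  stopifnot(fraction > 0, fraction <= 1, repeats >= 1)
  full <- rank_pairs(delta, survival, pairs = pairs, min_cluster = min_cluster)
  if (is.null(top_pairs)) top_pairs <- full$pair[full$adj_p < 0.05]
  if (length(top_pairs) == 0) {
    warn("no BH-significant pairs in the full cohort; nothing to report")
    return(tibble(pair = character(), repeats = integer(),
                  n_logrank_significant = integer(), n_cox_significant = integer(),
                  full_adj_p = double(), full_cox_p = double()))
  }
  ids <- intersect(rownames(delta$delta), survival$sample_id)
  n_keep <- floor(fraction * length(ids))
  if (n_keep < 10) abort("subsample too small; need floor(fraction * n) >= 10")

  hits_lr <- setNames(integer(length(top_pairs)), top_pairs)
  hits_cox <- setNames(integer(length(top_pairs)), top_pairs)
  for (r in seq_len(repeats)) {
    keep <- if (n_keep == length(ids)) ids else {
      set.seed((seed + r) %% .Machine$integer.max)
      sort(sample(ids, n_keep))
    }
    sub <- survival[survival$sample_id %in% keep, ]
    rk <- tryCatch(rank_pairs(delta, sub, pairs = pairs, min_cluster = min_cluster),
                   error = function(e) NULL)
    if (is.null(rk) || nrow(rk) == 0) next
    m <- rk[match(top_pairs, rk$pair), ]
    hits_lr <- hits_lr + (!is.na(m$adj_p) & m$adj_p < 0.05)
    hits_cox <- hits_cox + (!is.na(m$cox_p) & m$cox_p < 1e-4)
  }
  fm <- full[match(top_pairs, full$pair), ]
  tibble(pair = top_pairs, repeats = as.integer(repeats),
         n_logrank_significant = as.integer(hits_lr),
         n_cox_significant = as.integer(hits_cox),
         full_adj_p = fm$adj_p, full_cox_p = fm$cox_p)
}

#' Kaplan-Meier curve coordinates for a stratified pair
#'
#' Step-function coordinates of the Kaplan-Meier estimator for the Large
#' and Small delta-PCC clusters of one pair, ready for plotting or export.
#'
#' @param survival A survival tibble from [derive_survival()].
#' @param large_ids,small_ids Sample-id sets of the two clusters.
#' @return A tibble with `cluster`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(survival, large_ids, small_ids) {
  ids <- c(large_ids, small_ids)
  s <- survival[match(ids, survival$sample_id), ]
  grp <- factor(ifelse(ids %in% large_ids, "Large", "Small"), c("Large", "Small"))
  fit <- survfit(Surv(s$time_days, s$event) ~ grp)
  strata <- rep(names(fit$strata) %||% "grp=Large", fit$strata %||% length(fit$time))
  tibble(cluster = sub("^grp=", "", strata), time = fit$time, surv = fit$surv,
         n_risk = fit$n.risk, n_event = fit$n.event)
}
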