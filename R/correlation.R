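# p-value for a correlation coefficient from the exact t transform:
# t = r * sqrt((n-2) / (1-r^2)), df = n-2, two-sided. |r| = 1 -> p = 0.
r_to_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) >= 1 - 1e-15
  ok <- !is.na(r) & !perfect
  if (any(ok)) {
    tt <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
    p[ok] <- 2 * pt(-abs(tt), df = n - 2)
  }
  p[perfect] <- 0
  p
}

#' Correlation between two expression vectors with analytic p-value
#'
#' Pearson product-moment correlation, or Spearman's rank correlation
#' (Pearson on average-rank-transformed values). The two-sided p-value uses
#' the exact t transform `r * sqrt((n-2)/(1-r^2))` with `n - 2` degrees of
#' freedom; a perfect correlation gets `p = 0`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble with columns `estimate`, `n`, `statistic`,
#'   `p.value`, `method`.
#' @examples
#' cor_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
cor_test <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 observations for a correlation p-value")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: an input vector has zero variance")
  }
  r <- cor(x, y, method = method)
  stat <- if (abs(r) >= 1 - 1e-15) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  tibble(estimate = r, n = n, statistic = stat,
         p.value = r_to_p(r, n), method = method)
}

#' Compare two independent correlation coefficients (Fisher r-to-z)
#'
#' Tests whether two correlations differ, using Fisher's variance-
#' stabilizing transform: `z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal p-value. This is the
#' independent-groups comparison applied to the reference-panel correlation
#' and its single-sample-augmented counterpart (selection criterion 3).
#'
#' @param r1,r2 Correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (>= 4).
#' @return The two-sided p-value.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    abort("|r| = 1 has an infinite z-transform; correlations must lie strictly in (-1, 1)")
  }
  if (any(c(n1, n2) < 4)) abort("Fisher z comparison needs n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z))
}

# vectorized, clamped variant used inside select_pairs (matrix arguments)
fisher_z_p <- function(r1, n1, r2, n2) {
  cap <- 1 - 1e-15
  z <- (atanh(pmin(pmax(r1, -cap), cap)) - atanh(pmin(pmax(r2, -cap), cap))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * pnorm(-abs(z))
}

#' Single-sample correlation perturbation (delta-PCC) for one gene pair
#'
#' The perturbation a single tumor sample inflicts on a gene pair's
#' correlation in a normal reference panel:
#' `|PCC over reference + patient  -  PCC over reference|`. A patient whose
#' expression conforms to the reference co-expression structure leaves the
#' correlation nearly unchanged; a high-leverage sample that breaks it
#' produces a large delta.
#'
#' @param reference Numeric genes-by-samples matrix of the normal reference
#'   panel (>= 3 samples).
#' @param patient Named numeric vector of the patient's expression (names =
#'   gene symbols) or a one-column matrix.
#' @param gene_a,gene_b The gene pair (order irrelevant).
#' @param method Correlation kind, `"pearson"` or `"spearman"`.
#' @return The delta as a single nonnegative number in `[0, 2]`, or `NA`
#'   (with a warning) if either gene has zero variance before or after
#'   augmentation.
#' @export
delta_pcc <- function(reference, patient, gene_a, gene_b,
                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.matrix(patient)) patient <- setNames(patient[, 1], rownames(patient))
  genes <- c(gene_a, gene_b)
  if (!all(genes %in% rownames(reference)) || !all(genes %in% names(patient))) {
    abort("both pair genes must be present in the reference and the patient sample")
  }
  if (ncol(reference) < 3) abort("reference panel needs >= 3 samples")
  xa <- reference[gene_a, ]; xb <- reference[gene_b, ]
  if (sd(xa) == 0 || sd(xb) == 0 ||
      sd(c(xa, patient[gene_a])) == 0 || sd(c(xb, patient[gene_b])) == 0) {
    warn(sprintf("zero variance for pair %s; delta-PCC undefined",
                 paste(sort(genes), collapse = "_")))
    return(NA_real_)
  }
  r_ref <- cor(xa, xb, method = method)
  r_aug <- cor(c(xa, patient[gene_a]), c(xb, patient[gene_b]), method = method)
  abs(r_aug - r_ref)
}

#' Build the patients-by-pairs delta-PCC matrix
#'
#' For every patient and every gene pair, computes the reference-panel
#' correlation, the correlation with that one patient's sample appended to
#' the panel, and their absolute difference. The augmented correlations are
#' retained alongside the deltas because the pair-selection criteria need
#' them.
#'
#' @param reference Numeric genes-by-samples reference matrix (>= 3
#'   samples).
#' @param patients Numeric genes-by-samples tumor matrix for one patient
#'   group.
#' @param pairs A pair tibble from [gene_pairs()]/[all_gene_pairs()], or
#'   `NULL` for all pairs over the genes shared by both matrices.
#' @param method Correlation kind, `"pearson"` or `"spearman"`.
#' @param group_label Optional label stored with the result (e.g.
#'   `"wtTP53"`).
#' @return A `delta_pcc` object: deltas and augmented correlations as
#'   patients-by-pairs matrices, the reference correlations, the pair
#'   table, the panel size `reference_n`, and the correlation method.
#'   Undefined entries (zero-variance genes) are `NA` and counted in the
#'   `n_missing` field.
#' @export
build_delta_matrix <- function(reference, patients, pairs = NULL,
                               method = c("pearson", "spearman"),
                               group_label = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(reference), is.matrix(patients))
  if (is.null(pairs)) {
    pairs <- all_gene_pairs(intersect(rownames(reference), rownames(patients)))
  }
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  miss_ref <- setdiff(genes, rownames(reference))
  miss_pat <- setdiff(genes, rownames(patients))
  if (length(miss_ref) > 0 || length(miss_pat) > 0) {
    abort(sprintf("pair gene(s) absent from %s: %s",
                  if (length(miss_ref) > 0) "reference" else "patients",
                  paste(head(c(miss_ref, miss_pat), 5), collapse = ", ")))
  }
  pairs <- pairs %>% arrange(.data$pair)
  ref <- reference[genes, , drop = FALSE]
  pat <- patients[genes, , drop = FALSE]
  n_ref <- ncol(ref)
  if (n_ref < 3) abort("reference panel needs >= 3 samples")

  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  idx <- cbind(ia, ib)
  ref_R <- suppressWarnings(cor(t(ref), method = method))
  ref_r <- setNames(ref_R[idx], pairs$pair)

  n_pat <- ncol(pat)
  aug <- matrix(NA_real_, n_pat, nrow(pairs),
                dimnames = list(colnames(pat), pairs$pair))
  for (k in seq_len(n_pat)) {
    R <- suppressWarnings(cor(t(cbind(ref, pat[, k, drop = FALSE])), method = method))
    aug[k, ] <- R[idx]
  }
  delta <- abs(sweep(aug, 2, ref_r, "-"))
  n_missing <- sum(is.na(delta))
  if (n_missing > 0) {
    inform(sprintf("build_delta_matrix: %d undefined delta-PCC entr%s (zero-variance genes)",
                   n_missing, if (n_missing == 1) "y" else "ies"))
  }
  structure(list(
    delta = delta, aug_r = aug, ref_r = ref_r, pairs = pairs,
    reference_n = n_ref, method = method,
    group_label = group_label %||% NA_character_, n_missing = n_missing
  ), class = "delta_pcc")
}

#' @export
print.delta_pcc <- function(x, ...) {
  cat(sprintf("<delta_pcc> %d patients x %d gene pairs (%s, reference n = %d%s)\n",
              nrow(x$delta), ncol(x$delta), x$method, x$reference_n,
              if (!is.na(x$group_label)) paste0(", group ", x$group_label) else ""))
  invisible(x)
}

#' @describeIn build_delta_matrix Long-format view of the delta matrix:
#'   one row per (patient, pair) with columns `sample_id`, `pair`, `delta`,
#'   `aug_r`.
#' @param x A `delta_pcc` object.
#' @param ... Unused.
#' @export
tidy.delta_pcc <- function(x, ...) {
  as_tibble(x$delta, rownames = "sample_id") %>%
    pivot_longer(-"sample_id", names_to = "pair", values_to = "delta") %>%
    left_join(
      as_tibble(x$aug_r, rownames = "sample_id") %>%
        pivot_longer(-"sample_id", names_to = "pair", values_to = "aug_r"),
      by = c("sample_id", "pair")
    )
}

#' Select gene pairs perturbed by at least one patient
#'
#' Applies the three single-sample selection criteria at significance level
#' `alpha`, per (patient, pair):
#' 1. the reference-panel correlation is significant (`p < alpha` over the
#'    n normal samples);
#' 2. the correlation recomputed with the patient's sample appended (n + 1
#'    samples) is significant;
#' 3. the two correlations differ significantly by the Fisher r-to-z
#'    comparison.
#' A pair is retained when all three hold for at least one patient in the
#' group. Per-pair provenance records how many patients passed, or the
#' first criterion that eliminated the pair.
#'
#' @param delta A `delta_pcc` object from [build_delta_matrix()].
#' @param alpha Significance level for all three criteria (default 0.05).
#' @return A `pair_selection` tibble: `pair`, `gene_a`, `gene_b`, `ref_r`,
#'   `ref_p`, `n_patients_pass`, `retained`, `fail_reason`; attributes
#'   `alpha`, `reference_n`, `method`.
#' @export
select_pairs <- function(delta, alpha = 0.05) {
  stopifnot(inherits(delta, "delta_pcc"), alpha > 0, alpha <= 1)
  n <- delta$reference_n
  ref_p <- r_to_p(delta$ref_r, n)
  c1 <- !is.na(ref_p) & ref_p < alpha

  aug_p <- matrix(r_to_p(delta$aug_r, n + 1), nrow = nrow(delta$aug_r),
                  dimnames = dimnames(delta$aug_r))
  c2 <- !is.na(aug_p) & aug_p < alpha
  c3p <- fisher_z_p(matrix(delta$ref_r, nrow(delta$aug_r), ncol(delta$aug_r), byrow = TRUE),
                    n, delta$aug_r, n + 1)
  c3 <- !is.na(c3p) & c3p < alpha

  pass <- sweep(c2 & c3, 2, c1, "&")
  n_pass <- colSums(pass, na.rm = TRUE)
  any_c2 <- colSums(sweep(c2, 2, c1, "&"), na.rm = TRUE) > 0

  fail <- rep(NA_character_, length(c1))
  fail[!c1] <- "reference_pcc_not_significant"
  fail[c1 & !any_c2] <- "augmented_pcc_never_significant"
  fail[c1 & any_c2 & n_pass == 0] <- "correlation_change_never_significant"

  out <- delta$pairs %>%
    mutate(ref_r = unname(delta$ref_r), ref_p = unname(ref_p),
           n_patients_pass = unname(n_pass), retained = .data$n_patients_pass > 0,
           fail_reason = fail)
  if (!any(out$retained)) warn("select_pairs: no pair satisfied all three criteria")
  structure(out, alpha = alpha, reference_n = n, method = delta$method,
            class = c("pair_selection", class(out)))
}

#' Filter pairs by group-average perturbation
#'
#' Among the retained pairs, keeps those whose mean delta-PCC across the
#' group's patients strictly exceeds the grand mean of all (patient, pair)
#' delta-PCC entries over the retained pairs. Ranking downstream is per
#' pair, so the per-pair mean is the quantity compared against the grand
#' mean.
#'
#' @param delta A `delta_pcc` object.
#' @param selection A `pair_selection` from [select_pairs()]; pairs must be
#'   a subset of `delta`'s pairs.
#' @return The updated `pair_selection` with a `mean_delta` column; pairs
#'   at or below the grand mean get `retained = FALSE` and
#'   `fail_reason = "below_average_delta_pcc"`. The grand mean is attached
#'   as the `grand_mean_delta` attribute.
#' @export
average_delta_filter <- function(delta, selection) {
  stopifnot(inherits(delta, "delta_pcc"), inherits(selection, "pair_selection"))
  if (!all(selection$pair %in% colnames(delta$delta))) {
    abort("selection contains pairs absent from the delta matrix")
  }
  keep <- selection$pair[selection$retained]
  sub <- delta$delta[, keep, drop = FALSE]
  grand <- mean(sub, na.rm = TRUE)
  pair_means <- colMeans(sub, na.rm = TRUE)
  below <- names(pair_means)[!(pair_means > grand)]

  out <- selection %>%
    mutate(mean_delta = unname(pair_means[.data$pair]),
           fail_reason = ifelse(.data$pair %in% below, "below_average_delta_pcc",
                                .data$fail_reason),
           retained = .data$retained & !(.data$pair %in% below))
  attr(out, "alpha") <- attr(selection, "alpha")
  attr(out, "reference_n") <- attr(selection, "reference_n")
  attr(out, "method") <- attr(selection, "method")
  attr(out, "grand_mean_delta") <- grand
  class(out) <- class(selection)
  out
}

#' Persist a delta-PCC matrix as TSV plus a JSON metadata sidecar
#'
#' The TSV holds the patients-by-pairs deltas at full precision; the
#' sidecar (`<path>.json`) records the reference panel size, correlation
#' method, group label, and — when a selection is supplied — the selection
#' level and per-pair filter decisions.
#'
#' @param delta A `delta_pcc` object.
#' @param path Output TSV path.
#' @param selection Optional `pair_selection` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_delta_matrix <- function(delta, path, selection = NULL) {
  stopifnot(inherits(delta, "delta_pcc"))
  df <- tibble(sample_id = rownames(delta$delta)) %>%
    bind_cols(as_tibble(apply(delta$delta, 2, format_full, simplify = FALSE)))
  readr::write_tsv(df, path, progress = FALSE)
  meta <- list(
    reference_n = delta$reference_n, method = delta$method,
    group_label = delta$group_label, n_missing = delta$n_missing,
    comparison_test = "fisher_z_independent_groups"
  )
  if (!is.null(selection)) {
    meta$alpha <- attr(selection, "alpha")
    meta$grand_mean_delta <- attr(selection, "grand_mean_delta")
    meta$selection <- as.data.frame(selection)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a delta-PCC matrix written by [write_delta_matrix()]
#'
#' @param path Path to the TSV file (the `.json` sidecar must sit beside
#'   it).
#' @return A `delta_pcc` object (without augmented correlations, which are
#'   not persisted); if the sidecar holds a selection it is attached as the
#'   `selection` field.
#' @export
read_delta_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("delta matrix not found: ", path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) abort(paste0("delta matrix sidecar not found: ", side))
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb$sample_id
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  labels <- colnames(m)
  parts <- stringr::str_split_fixed(labels, "_", 2)
  obj <- structure(list(
    delta = m, aug_r = NULL, ref_r = NULL,
    pairs = tibble(gene_a = parts[, 1], gene_b = parts[, 2], pair = labels),
    reference_n = meta$reference_n, method = meta$method,
    group_label = meta$group_label %||% NA_character_,
    n_missing = sum(is.na(m))
  ), class = "delta_pcc")
  if (!is.null(meta$selection)) {
    sel <- as_tibble(meta$selection)
    obj$selection <- structure(sel, alpha = meta$alpha,
                               reference_n = meta$reference_n, method = meta$method,
                               grand_mean_delta = meta$grand_mean_delta,
                               class = c("pair_selection", class(sel)))
  }
  obj
}
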