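#' Canonical gene pairs
#'
#' A gene pair is identified by its two gene symbols in lexicographic order
#' and by the label `"<gene_a>_<gene_b>"` (e.g. `"MAPK10_PTK6"`). All
#' pair-indexed results in the package use this canonical form, so a pair
#' entered in either order always maps to the same row.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled to a
#'   common length). Pairs with `gene_a == gene_b` are an error.
#' @return A tibble with columns `gene_a`, `gene_b`, `pair` (the canonical
#'   label), one row per input pair.
#' @examples
#' gene_pairs("PTK6", "MAPK10") # canonicalized to MAPK10 < PTK6
#' @export
gene_pairs <- function(gene_a, gene_b) {
  n <- max(length(gene_a), length(gene_b))
  gene_a <- rep_len(as.character(gene_a), n)
  gene_b <- rep_len(as.character(gene_b), n)
  if (any(gene_a == gene_b)) {
    abort("a gene pair must consist of two distinct genes")
  }
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  tibble(gene_a = a, gene_b = b, pair = paste(a, b, sep = "_"))
}

#' All pairs over a gene universe
#'
#' Enumerates every unordered pair of distinct genes, in lexicographic order
#' of the canonical pair label, which fixes the column order of all
#' downstream pair-indexed matrices.
#'
#' @param genes Character vector of unique gene symbols (>= 2).
#' @return A tibble as from [gene_pairs()], `choose(length(genes), 2)` rows.
#' @export
all_gene_pairs <- function(genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) abort("`genes` contains duplicated symbols")
  if (length(genes) < 2) abort("need at least 2 genes to form pairs")
  g <- sort(genes)
  idx <- utils::combn(length(g), 2)
  gene_pairs(g[idx[1, ]], g[idx[2, ]]) %>% arrange(.data$pair)
}

#' Number of single-sample delta-PCC values for a cohort
#'
#' Each of `n_patients` tumor samples contributes one delta-PCC per
#' unordered pair of core genes, so the total enumeration size is
#' `n_patients * choose(n_genes, 2)`. For 496 patients and 516 core genes
#' this is 65,903,520 values.
#'
#' @param n_patients Number of tumor samples (nonnegative integer).
#' @param n_genes Number of core genes (>= 2).
#' @return The exact count as a double (exact for all realistic sizes:
#'   integer-valued doubles are exact below 2^53).
#' @examples
#' count_delta_pccs(496, 516)
#' @export
count_delta_pccs <- function(n_patients, n_genes) {
  stopifnot(length(n_patients) == 1, length(n_genes) == 1)
  n_patients <- as.numeric(n_patients)
  n_genes <- as.numeric(n_genes)
  if (n_patients < 0 || n_patients != floor(n_patients)) {
    abort("`n_patients` must be a nonnegative integer")
  }
  if (n_genes < 2 || n_genes != floor(n_genes)) {
    abort("`n_genes` must be an integer >= 2")
  }
  n_patients * (n_genes * (n_genes - 1) / 2)
}
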