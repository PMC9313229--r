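#' Read a genes-by-samples expression matrix from TSV
#'
#' The file layout is the one used for the cohort artifacts throughout the
#' package: a header row of sample ids, the first column holding gene
#' symbols, every other cell a decimal number on a log-like scale. Values
#' are taken as already normalized; set `log2_transform = TRUE` to apply
#' `log2(x + 1)` on read (Pearson correlation is scale-sensitive, so the
#' transform is an explicit, logged choice rather than a guess).
#'
#' Duplicate gene symbols are collapsed by keeping the row with the highest
#' mean expression (reported via a message). When `gene_list` is given the
#' matrix is restricted to it; genes absent from the file are reported with
#' a warning, and an empty intersection is an error.
#'
#' @param path Path to the TSV file.
#' @param gene_list Optional character vector of gene symbols to retain.
#' @param log2_transform Apply `log2(x + 1)` to all values (default `FALSE`).
#' @return A numeric matrix with gene symbols as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path, gene_list = NULL, log2_transform = FALSE) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("expression TSV needs a gene column plus >= 1 sample column")
  genes <- as.character(raw[[1]])
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) abort("duplicate sample ids in expression header")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                  vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyNA(num)) abort("expression matrix contains missing values")
  rownames(num) <- genes
  colnames(num) <- samples

  if (anyDuplicated(genes)) {
    means <- rowMeans(num)
    keep <- order(-means)                       # highest-mean row first
    keep <- keep[!duplicated(genes[keep])]
    dropped <- sum(duplicated(genes))
    inform(sprintf("collapsed %d duplicated gene row(s), keeping the highest-mean row", dropped))
    num <- num[sort(keep), , drop = FALSE]
  }
  if (!is.null(gene_list)) {
    gene_list <- unique(as.character(gene_list))
    missing <- setdiff(gene_list, rownames(num))
    if (length(missing) == length(gene_list)) {
      abort("none of the requested genes are present in the expression file")
    }
    if (length(missing) > 0) {
      warn(sprintf("%d requested gene(s) absent from expression file: %s",
                   length(missing), paste(head(missing, 10), collapse = ", ")))
    }
    num <- num[gene_list[gene_list %in% rownames(num)], , drop = FALSE]
  }
  if (log2_transform) num <- log2(num + 1)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: round-trips finite values bit-identically
#' (full decimal precision, 17 significant digits).
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- tibble(gene = rownames(expr)) %>%
    bind_cols(as_tibble(apply(expr, 2, format_full, simplify = FALSE)))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# full-precision decimal rendering so write -> read is bit-identical
format_full <- function(x) {
  formatC(x, format = "g", digits = 17)
}

#' Read a core gene list
#'
#' One gene symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the gene list file.
#' @return Character vector of unique gene symbols, file order preserved.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("gene list file not found: ", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  unique(lines[lines != ""])
}

.vital_levels <- c("alive", "dead")
.tp53_levels <- c("wild_type", "mutated")
.subtype_levels <- c("LuminalA", "LuminalB", "HER2", "Basal", "NormalLike")

#' Read a clinical/survival table from TSV
#'
#' Expected columns: `sample_id`, `days_to_death`, `days_to_last_follow_up`,
#' `vital_status` (`alive`/`dead`), `tp53_status` (`wild_type`/`mutated`),
#' and optionally `subtype` (PAM50-style label). Missing values may be
#' encoded as empty strings or `NA`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above, day fields as integers.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("clinical file not found: ", path))
  cl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = c("", "NA"), progress = FALSE)
  required <- c("sample_id", "days_to_death", "days_to_last_follow_up",
                "vital_status", "tp53_status")
  missing <- setdiff(required, colnames(cl))
  if (length(missing) > 0) {
    abort(paste0("clinical table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in c("days_to_death", "days_to_last_follow_up")) {
    num <- suppressWarnings(as.integer(cl[[col]]))
    bad <- !is.na(cl[[col]]) & is.na(num)
    if (any(bad)) {
      abort(sprintf("non-integer value '%s' in column %s for sample '%s'",
                    cl[[col]][bad][1], col, cl$sample_id[bad][1]))
    }
    cl[[col]] <- num
  }
  if (anyDuplicated(cl$sample_id)) abort("duplicate sample ids in clinical table")
  bad_vs <- setdiff(unique(cl$vital_status[!is.na(cl$vital_status)]), .vital_levels)
  if (length(bad_vs) > 0) {
    abort(paste0("unknown vital_status value(s): ", paste(bad_vs, collapse = ", ")))
  }
  if (!"subtype" %in% colnames(cl)) cl$subtype <- NA_character_
  as_tibble(cl)
}

#' Derive overall-survival records from clinical fields
#'
#' Overall survival is the number of days from initial diagnosis to death
#' (event observed) or to last follow-up (censored). For deceased patients
#' `time_days = days_to_death`; for living patients
#' `time_days = days_to_last_follow_up`. Rows whose resulting time is
#' missing or nonpositive are dropped — zero-length follow-up carries no
#' survival information and destabilizes partial-likelihood tie handling —
#' and the number of drops is reported and attached as the `n_dropped`
#' attribute.
#'
#' @param clinical A clinical tibble as from [read_clinical()].
#' @return A tibble with columns `sample_id`, `time_days` (positive
#'   integer), `event` (logical, `TRUE` = death observed), carrying an
#'   `n_dropped` attribute.
#' @export
derive_survival <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  surv <- clinical %>%
    mutate(
      event = .data$vital_status == "dead",
      time_days = ifelse(.data$event, .data$days_to_death, .data$days_to_last_follow_up)
    ) %>%
    select("sample_id", "time_days", "event")
  keep <- !is.na(surv$event) & !is.na(surv$time_days) & surv$time_days > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("derive_survival: dropped %d sample(s) with missing or nonpositive survival time", n_dropped))
  }
  out <- surv[keep, , drop = FALSE]
  out$time_days <- as.integer(out$time_days)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Partition a cohort by TP53 mutation status
#'
#' @param clinical A clinical tibble with a `tp53_status` column
#'   (`wild_type` / `mutated`); any other value is an error naming the
#'   offending sample.
#' @return A named list `list(wt_ids =, mut_ids =)` of disjoint, exhaustive
#'   sample-id vectors. A warning is emitted if either group is empty.
#' @export
split_cohort <- function(clinical) {
  stopifnot(is.data.frame(clinical), all(c("sample_id", "tp53_status") %in% colnames(clinical)))
  bad <- which(!(clinical$tp53_status %in% .tp53_levels))
  if (length(bad) > 0) {
    abort(sprintf("unknown tp53_status '%s' for sample '%s'",
                  clinical$tp53_status[bad[1]], clinical$sample_id[bad[1]]))
  }
  wt <- clinical$sample_id[clinical$tp53_status == "wild_type"]
  mut <- clinical$sample_id[clinical$tp53_status == "mutated"]
  if (length(wt) == 0 || length(mut) == 0) {
    warn("one TP53 group is empty")
  }
  list(wt_ids = wt, mut_ids = mut)
}

#' Cohort composition by TP53 status and subtype
#'
#' Tabulates group sizes and percentages: each TP53 group as a percentage
#' of the whole cohort, and each subtype as a percentage of its TP53 group.
#' Percentages are rounded to one decimal, the convention used in cohort
#' description tables.
#'
#' @param clinical A clinical tibble.
#' @return A tibble with columns `tp53_status`, `subtype` (`NA` for the
#'   group-level rows), `n`, and `pct` (of the cohort for group rows, of
#'   the group for subtype rows).
#' @export
summarize_cohort <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  total <- nrow(clinical)
  groups <- clinical %>%
    count(.data$tp53_status) %>%
    mutate(subtype = NA_character_, pct = round(100 * .data$n / total, 1))
  subtypes <- clinical %>%
    filter(!is.na(.data$subtype)) %>%
    count(.data$tp53_status, .data$subtype) %>%
    group_by(.data$tp53_status) %>%
    mutate(pct = round(100 * .data$n / sum(.data$n), 1)) %>%
    ungroup()
  bind_rows(groups, subtypes) %>%
    select("tp53_status", "subtype", "n", "pct") %>%
    arrange(.data$tp53_status, !is.na(.data$subtype), .data$subtype)
}

#' Write a per-pair survival result table
#'
#' Serializes the ranked gene-pair results to TSV with columns `pair`,
#' `n_large`, `n_small`, `logrank_p`, `adj_p`, `hazard_ratio`, `cox_p`,
#' `concordance`, `hr_infinite`, sorted by hazard ratio descending (the
#' presentation order of the headline result tables). An infinite hazard
#' ratio (monotone Cox likelihood) is written as `inf` with the
#' `hr_infinite` flag set.
#'
#' @param results A tibble as produced by [rank_pairs()]; may be empty.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(results, path) {
  cols <- c("pair", "n_large", "n_small", "logrank_p", "adj_p",
            "hazard_ratio", "cox_p", "concordance", "hr_infinite")
  if (nrow(results) == 0) {
    readr::write_tsv(tibble(!!!setNames(rep(list(character(0)), length(cols)), cols)),
                     path, progress = FALSE)
    return(invisible(path))
  }
  stopifnot(all(cols %in% colnames(results)))
  out <- results %>%
    arrange(desc(.data$hazard_ratio)) %>%
    mutate(
      hazard_ratio = ifelse(is.infinite(.data$hazard_ratio), "inf",
                            format_full(.data$hazard_ratio)),
      across(c("logrank_p", "adj_p", "cox_p", "concordance"), format_full)
    ) %>%
    select(all_of(cols))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a per-pair survival result table written by [write_pair_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with the numeric columns restored (`inf` parsed back to
#'   `Inf`).
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) abort(paste0("pair table not found: ", path))
  tb <- readr::read_tsv(path, col_types = readr::cols(
    pair = readr::col_character(),
    hazard_ratio = readr::col_character(),
    hr_infinite = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  tb$hazard_ratio <- ifelse(tb$hazard_ratio == "inf", Inf, as.numeric(tb$hazard_ratio))
  tb$n_large <- as.integer(tb$n_large)
  tb$n_small <- as.integer(tb$n_small)
  tb
}
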