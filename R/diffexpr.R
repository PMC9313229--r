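#' Two-group differential expression (Welch t-test per gene)
#'
#' Compares each gene's expression between the wild-type and mutated TP53
#' groups with the unequal-variance (Welch) two-sample t-test and adjusts
#' p-values by Benjamini-Hochberg across all genes (one family). The fold
#' change is taken on the log2 scale the expression is assumed to be on:
#' `log2_fc = mean(mut) - mean(wt)`, so genes higher in the mutated group
#' have positive fold change (`direction = "up_in_mut"`).
#'
#' Degenerate genes follow fixed conventions: both groups constant with
#' equal means gives `p = 1`; both constant with different means gives
#' `p = 0` (perfect separation).
#'
#' @param expr Numeric genes-by-samples matrix on a log2-like scale.
#' @param wt_ids,mut_ids Sample ids of the two groups (>= 2 each, present
#'   in `expr`).
#' @return A `de_result` tibble: `gene`, `log2_fc`, `statistic`,
#'   `p_value`, `adj_p`, `direction`, sorted by `adj_p`.
#' @export
differential_expression <- function(expr, wt_ids, mut_ids) {
  stopifnot(is.matrix(expr))
  missing <- setdiff(c(wt_ids, mut_ids), colnames(expr))
  if (length(missing) > 0) {
    abort(paste0("sample id(s) absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (length(wt_ids) < 2 || length(mut_ids) < 2) {
    abort("both groups need >= 2 samples for a t-test")
  }
  wt <- expr[, wt_ids, drop = FALSE]
  mut <- expr[, mut_ids, drop = FALSE]
  n1 <- ncol(wt); n2 <- ncol(mut)
  m1 <- rowMeans(wt); m2 <- rowMeans(mut)
  v1 <- apply(wt, 1, var); v2 <- apply(mut, 1, var)

  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  # both groups constant: equal means -> no evidence (p = 1); different
  # means -> perfect separation (p = 0)
  degen <- se2 == 0
  p[degen & (m1 == m2)] <- 1
  p[degen & (m1 != m2)] <- 0
  tt[degen] <- ifelse(m2[degen] == m1[degen], 0, sign(m2[degen] - m1[degen]) * Inf)

  out <- tibble(
    gene = rownames(expr), log2_fc = unname(m2 - m1), statistic = unname(tt),
    p_value = unname(p), adj_p = bh_adjust(unname(p)),
    direction = unname(ifelse(m2 - m1 >= 0, "up_in_mut", "down_in_mut"))
  ) %>% arrange(.data$adj_p, .data$p_value, .data$gene)
  class(out) <- c("de_result", class(out))
  out
}

#' Filter differential-expression results
#'
#' Keeps genes changed more than `2^fc_threshold`-fold between the groups
#' (`|log2_fc| > fc_threshold`; the default 1 means "more than twice in
#' one group than the other") with BH-adjusted p below `alpha`.
#'
#' @param results A `de_result` tibble from [differential_expression()].
#' @param fc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha Adjusted-p gate (default 0.05).
#' @return The filtered tibble.
#' @export
de_filter <- function(results, fc_threshold = 1, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  results %>% filter(abs(.data$log2_fc) > fc_threshold, .data$adj_p < alpha)
}

#' Volcano plot of a differential-expression table
#'
#' log2 fold change against -log10 p-value, colored by direction for
#' genes passing both gates.
#'
#' @param object A `de_result` tibble.
#' @param fc_threshold,alpha Gates drawn and used for coloring (defaults
#'   1 and 0.05, as in [de_filter()]).
#' @param label_top Number of top genes (by adjusted p) to label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, fc_threshold = 1, alpha = 0.05,
                               label_top = 10, ...) {
  dat <- object %>%
    mutate(status = case_when(
      .data$adj_p < alpha & .data$log2_fc > fc_threshold ~ "up_in_mut",
      .data$adj_p < alpha & .data$log2_fc < -fc_threshold ~ "down_in_mut",
      TRUE ~ "not_significant"))
  lab <- dat %>% filter(.data$status != "not_significant") %>%
    arrange(.data$adj_p) %>% head(label_top)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(pmax(.data$p_value, 1e-300)))) +
    ggplot2::geom_point(ggplot2::aes(color = .data$status), size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc_threshold, fc_threshold), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 2.8) +
    ggplot2::scale_color_manual(values = c(up_in_mut = "#B2182B",
                                           down_in_mut = "#2166AC",
                                           not_significant = "grey70")) +
    ggplot2::labs(x = "log2 fold change (mut - wt)", y = "-log10 p-value",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Write the volcano table as TSV
#'
#' Columns `gene`, `log2_fc`, `p_value`, `adj_p`, `direction` — the inputs
#' of a volcano plot.
#'
#' @param results A `de_result` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volcano_table <- function(results, path) {
  results %>%
    mutate(across(c("log2_fc", "p_value", "adj_p"), format_full)) %>%
    select("gene", "log2_fc", "p_value", "adj_p", "direction") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
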