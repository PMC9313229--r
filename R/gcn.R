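#' Build a prognostic-information-enriched gene correlation network
#'
#' Nodes are the genes of the retained pairs; each edge carries the
#' group-level correlation of its pair (computed across the group's tumor
#' samples) as a signed weight with its analytic p-value. Each node is
#' annotated with the prognostic behavior of its gene: a univariate Cox
#' model is fitted on the gene's expression, standardized to unit
#' variance, as a continuous covariate, and the gene is labeled
#' `unfavorable` (hazard rises with expression, `HR > 1`, Cox p < alpha),
#' `favorable` (`HR < 1`, Cox p < alpha), or `none`; Harrell's concordance
#' of that per-gene model is stored alongside. Genes with zero variance
#' keep their node but get missing annotations.
#'
#' @param group_expression Numeric genes-by-samples matrix of one patient
#'   group.
#' @param pairs Retained pairs: a `pair_selection` (retained rows used), a
#'   pair tibble, or a character vector of labels.
#' @param survival A survival tibble from [derive_survival()]; samples are
#'   matched by id to the expression columns.
#' @param alpha Significance level for the prognostic-type call and for
#'   downstream sign comparisons (default 0.05).
#' @param method Correlation kind for edge weights.
#' @param group_label Label stored on the network (e.g. `"wtTP53"`).
#' @return A `gcn` object: `nodes` tibble (`gene`, `prognostic_type`,
#'   `concordance`, `cox_hr`, `cox_p`), `edges` tibble (`gene_a`,
#'   `gene_b`, `pair`, `weight`, `sign`, `p_value`), `group_label`,
#'   `alpha`.
#' @export
build_gcn <- function(group_expression, pairs, survival, alpha = 0.05,
                      method = c("pearson", "spearman"), group_label = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(group_expression))
  if (inherits(pairs, "pair_selection")) pairs <- pairs[pairs$retained, ]
  if (is.character(pairs)) {
    parts <- stringr::str_split_fixed(pairs, "_", 2)
    pairs <- tibble(gene_a = parts[, 1], gene_b = parts[, 2], pair = pairs)
  }
  pairs <- as_tibble(pairs)[, c("gene_a", "gene_b", "pair")]
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  missing <- setdiff(genes, rownames(group_expression))
  if (length(missing) > 0) {
    abort(paste0("pair gene(s) absent from expression matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  n_samp <- ncol(group_expression)

  edges <- if (nrow(pairs) > 0) {
    pairs %>%
      mutate(weight = map2_dbl_(pairs$gene_a, pairs$gene_b, function(a, b) {
               suppressWarnings(cor(group_expression[a, ], group_expression[b, ],
                                    method = method))
             }),
             sign = ifelse(.data$weight > 0, "positive", "negative"),
             p_value = r_to_p(.data$weight, n_samp)) %>%
      arrange(.data$pair)
  } else {
    tibble(gene_a = character(), gene_b = character(), pair = character(),
           weight = double(), sign = character(), p_value = double())
  }

  ids <- intersect(colnames(group_expression), survival$sample_id)
  sv <- survival[match(ids, survival$sample_id), ]
  annotate <- function(g) {
    x <- group_expression[g, ids]
    if (length(ids) < 3 || sd(x) == 0 || sum(sv$event) == 0) {
      inform(sprintf("gene %s: prognostic annotation unavailable", g))
      return(tibble(gene = g, prognostic_type = NA_character_,
                    concordance = NA_real_, cox_hr = NA_real_, cox_p = NA_real_))
    }
    cx <- tryCatch(
      suppressWarnings(cox_univariate(sv$time_days, sv$event, as.numeric(scale(x)))),
      error = function(e) NULL)
    if (is.null(cx) || cx$hr_infinite) {
      return(tibble(gene = g, prognostic_type = NA_character_,
                    concordance = NA_real_, cox_hr = NA_real_, cox_p = NA_real_))
    }
    type <- if (cx$p.value < alpha) {
      if (cx$hazard_ratio > 1) "unfavorable" else "favorable"
    } else "none"
    tibble(gene = g, prognostic_type = type, concordance = cx$concordance,
           cox_hr = cx$hazard_ratio, cox_p = cx$p.value)
  }
  nodes <- if (length(genes) > 0) list_rbind(map(genes, annotate)) else
    tibble(gene = character(), prognostic_type = character(),
           concordance = double(), cox_hr = double(), cox_p = double())

  structure(list(nodes = nodes, edges = edges,
                 group_label = group_label %||% NA_character_,
                 alpha = alpha, method = method),
            class = "gcn")
}

# local two-argument map to keep purrr usage simple
map2_dbl_ <- function(a, b, f) vapply(seq_along(a), function(i) f(a[i], b[i]), numeric(1))

#' @export
print.gcn <- function(x, ...) {
  cat(sprintf("<gcn%s> %d genes, %d edges (%d positive / %d negative)\n",
              if (!is.na(x$group_label)) paste0(" ", x$group_label) else "",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' @describeIn build_gcn Edge table of the network as a tibble.
#' @param x A `gcn` object.
#' @param ... Unused.
#' @export
tidy.gcn <- function(x, ...) x$edges

#' @describeIn build_gcn One-row network summary (node/edge counts, sign
#'   balance, prognostic node counts).
#' @export
glance.gcn <- function(x, ...) {
  tibble(group_label = x$group_label,
         n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_positive = sum(x$edges$sign == "positive"),
         n_negative = sum(x$edges$sign == "negative"),
         n_favorable = sum(x$nodes$prognostic_type == "favorable", na.rm = TRUE),
         n_unfavorable = sum(x$nodes$prognostic_type == "unfavorable", na.rm = TRUE))
}

#' Compare two enriched gene correlation networks
#'
#' Classifies every distinct edge of the two networks: present in both
#' with the same correlation sign; present in both with opposite signs
#' (reported only when both edges are individually significant at the
#' networks' alpha — a sign flip between two noise-level correlations is
#' not a finding; otherwise the edge is classed `common_uncertain`); or
#' exclusive to one network. Shared and exclusive node sets are reported
#' likewise.
#'
#' @param gcn_a,gcn_b Two `gcn` objects.
#' @return A `gcn_comparison` list: `edges` (tibble with `pair`,
#'   `weight_a`, `weight_b`, `p_a`, `p_b`, `category`), `nodes` (tibble
#'   with `gene`, `in_a`, `in_b`), `counts` (one-row tibble of all set
#'   sizes), and the two group labels.
#' @export
compare_gcns <- function(gcn_a, gcn_b) {
  stopifnot(inherits(gcn_a, "gcn"), inherits(gcn_b, "gcn"))
  alpha <- max(gcn_a$alpha, gcn_b$alpha)
  ea <- gcn_a$edges %>% select("pair", weight_a = "weight", p_a = "p_value")
  eb <- gcn_b$edges %>% select("pair", weight_b = "weight", p_b = "p_value")
  edges <- full_join(ea, eb, by = "pair") %>%
    mutate(category = case_when(
      is.na(.data$weight_b) ~ "a_only",
      is.na(.data$weight_a) ~ "b_only",
      sign(.data$weight_a) == sign(.data$weight_b) ~ "common_same_sign",
      .data$p_a < alpha & .data$p_b < alpha ~ "common_opposite_sign",
      TRUE ~ "common_uncertain"
    )) %>%
    arrange(.data$category, .data$pair)
  nodes <- full_join(
    gcn_a$nodes %>% transmute(gene = .data$gene, in_a = TRUE),
    gcn_b$nodes %>% transmute(gene = .data$gene, in_b = TRUE),
    by = "gene") %>%
    mutate(in_a = !is.na(.data$in_a), in_b = !is.na(.data$in_b)) %>%
    arrange(.data$gene)
  counts <- tibble(
    n_common_same_sign = sum(edges$category == "common_same_sign"),
    n_common_opposite_sign = sum(edges$category == "common_opposite_sign"),
    n_common_uncertain = sum(edges$category == "common_uncertain"),
    n_a_only = sum(edges$category == "a_only"),
    n_b_only = sum(edges$category == "b_only"),
    n_nodes_shared = sum(nodes$in_a & nodes$in_b),
    n_nodes_a_only = sum(nodes$in_a & !nodes$in_b),
    n_nodes_b_only = sum(nodes$in_b & !nodes$in_a)
  )
  structure(list(edges = edges, nodes = nodes, counts = counts,
                 label_a = gcn_a$group_label, label_b = gcn_b$group_label),
            class = "gcn_comparison")
}

#' @export
print.gcn_comparison <- function(x, ...) {
  cat(sprintf("<gcn_comparison> %s vs %s\n", x$label_a, x$label_b))
  print(x$counts)
  invisible(x)
}

#' @describeIn compare_gcns Full per-edge classification table.
#' @param x A `gcn_comparison` object.
#' @param ... Unused.
#' @export
tidy.gcn_comparison <- function(x, ...) x$edges

#' @describeIn compare_gcns Set-size summary of the comparison.
#' @export
glance.gcn_comparison <- function(x, ...) x$counts

# gcn -> igraph with typed node/edge attributes
gcn_to_igraph <- function(gcn) {
  igraph::graph_from_data_frame(
    d = gcn$edges %>% select("gene_a", "gene_b", "weight", "sign", "p_value"),
    directed = FALSE,
    vertices = gcn$nodes %>% select("gene", "prognostic_type", "concordance",
                                    "cox_hr", "cox_p"))
}

#' Export an enriched GCN as GraphML
#'
#' Writes the network with typed attributes: `weight`, `sign`, `p_value`
#' on edges; `prognostic_type`, `concordance`, `cox_hr`, `cox_p` on nodes.
#' Missing numeric annotations are encoded as NaN (the GraphML encoding
#' igraph uses for `NA`) and restored to `NA` by [import_graphml()], so
#' export/import round-trips attribute-for-attribute.
#'
#' @param gcn A `gcn` object.
#' @param path Output path (`.graphml`).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(gcn, path) {
  stopifnot(inherits(gcn, "gcn"))
  g <- gcn_to_igraph(gcn)
  igraph::graph_attr(g, "group_label") <- gcn$group_label %||% ""
  igraph::graph_attr(g, "alpha") <- gcn$alpha
  igraph::graph_attr(g, "method") <- gcn$method
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import a GraphML network written by [export_graphml()]
#'
#' @param path Path to the `.graphml` file.
#' @return A `gcn` object.
#' @export
import_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("GraphML file not found: ", path))
  g <- igraph::read_graph(path, format = "graphml")
  vnames <- igraph::vertex_attr(g, "name")
  nan_to_na <- function(x) { x[is.nan(x)] <- NA_real_; x }
  nodes <- tibble(
    gene = vnames,
    prognostic_type = igraph::vertex_attr(g, "prognostic_type") %||% NA_character_,
    concordance = nan_to_na(igraph::vertex_attr(g, "concordance") %||% NA_real_),
    cox_hr = nan_to_na(igraph::vertex_attr(g, "cox_hr") %||% NA_real_),
    cox_p = nan_to_na(igraph::vertex_attr(g, "cox_p") %||% NA_real_)
  ) %>% arrange(.data$gene)
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el) > 0) {
    gene_pairs(el[, 1], el[, 2]) %>%
      mutate(weight = igraph::edge_attr(g, "weight"),
             sign = igraph::edge_attr(g, "sign"),
             p_value = igraph::edge_attr(g, "p_value")) %>%
      arrange(.data$pair)
  } else {
    tibble(gene_a = character(), gene_b = character(), pair = character(),
           weight = double(), sign = character(), p_value = double())
  }
  lbl <- igraph::graph_attr(g, "group_label")
  structure(list(nodes = nodes, edges = edges,
                 group_label = if (is.null(lbl) || identical(lbl, "")) NA_character_ else lbl,
                 alpha = igraph::graph_attr(g, "alpha") %||% 0.05,
                 method = igraph::graph_attr(g, "method") %||% "pearson"),
            class = "gcn")
}

#' Export a GCN edge list as TSV
#'
#' Columns: `gene_a`, `gene_b`, `weight`, `sign`, `p_value`.
#'
#' @param gcn A `gcn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_edgelist <- function(gcn, path) {
  stopifnot(inherits(gcn, "gcn"))
  gcn$edges %>%
    mutate(weight = format_full(.data$weight), p_value = format_full(.data$p_value)) %>%
    select("gene_a", "gene_b", "weight", "sign", "p_value") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Plot an enriched GCN
#'
#' Force-directed layout with edge color by correlation sign, edge width
#' by |weight|, and node color by prognostic type.
#'
#' @param object A `gcn` object.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gcn <- function(object, seed = 1, ...) {
  g <- gcn_to_igraph(object)
  set.seed(seed)
  # signed correlation weights are not distances; layout on topology only
  xy <- igraph::layout_with_fr(g, weights = NA)
  lay <- tibble(gene = igraph::vertex_attr(g, "name"), x = xy[, 1], y = xy[, 2]) %>%
    left_join(object$nodes, by = "gene") %>%
    mutate(prognostic_type = .data$prognostic_type %||% "none")
  ed <- object$edges %>%
    left_join(lay %>% select("gene", xa = "x", ya = "y"), by = c(gene_a = "gene")) %>%
    left_join(lay %>% select("gene", xb = "x", yb = "y"), by = c(gene_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   color = .data$sign, linewidth = abs(.data$weight)), alpha = 0.7) +
    ggplot2::geom_point(data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$prognostic_type),
      shape = 21, size = 4) +
    ggplot2::geom_text(data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 2.8) +
    ggplot2::scale_color_manual(values = c(positive = "#2166AC", negative = "#B2182B")) +
    ggplot2::scale_fill_manual(values = c(favorable = "#4DAF4A",
                                          unfavorable = "#E41A1C", none = "grey80"),
                               na.value = "white") +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0("Enriched GCN",
                                 if (!is.na(object$group_label)) paste0(": ", object$group_label) else ""))
}
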