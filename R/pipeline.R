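#' Pipeline run configuration
#'
#' Collects paths and parameters for the staged pipeline. All artifacts
#' live under `dir` by default; any individual path can be overridden.
#' Defaults are recorded in each stage's JSON manifest, so every artifact
#' is reproducible from its manifest alone.
#'
#' @param dir Artifact directory.
#' @param alpha Significance level used by pair selection, prognostic
#'   annotation, and significance calls (default 0.05).
#' @param fc_threshold Absolute log2 fold-change gate for differential
#'   expression (default 1).
#' @param min_cluster Minimum cluster size in per-pair stratification
#'   (default 5).
#' @param correlation_kind `"pearson"` (default) or `"spearman"`.
#' @param seed Integer seed for every stochastic stage.
#' @param log2_transform Apply `log2(x + 1)` when reading expression
#'   (default `FALSE`; synthetic cohorts are already on a log-like scale).
#' @param preset Benchmark preset for the simulate stage.
#' @param subsample_fraction,subsample_repeats Robustness-stage settings
#'   (defaults 0.9 and 3).
#' @param ... Path overrides: `expression`, `reference`, `clinical`,
#'   `genes`, or any `<artifact>` path used by a stage.
#' @return A `run_config` list.
#' @export
run_config <- function(dir = ".", alpha = 0.05, fc_threshold = 1,
                       min_cluster = 5,
                       correlation_kind = c("pearson", "spearman"),
                       seed = 1, log2_transform = FALSE,
                       preset = c("small", "paper_shaped"),
                       subsample_fraction = 0.9, subsample_repeats = 3, ...) {
  correlation_kind <- match.arg(correlation_kind)
  preset <- match.arg(preset)
  stopifnot(alpha > 0, alpha < 1)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    reference = file.path(dir, "reference.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    genes = file.path(dir, "genes.txt"),
    delta_wt = file.path(dir, "delta_wt.tsv"),
    delta_mut = file.path(dir, "delta_mut.tsv"),
    pairs_wt = file.path(dir, "pairs_wt.tsv"),
    pairs_mut = file.path(dir, "pairs_mut.tsv"),
    gcn_wt = file.path(dir, "gcn_wt.graphml"),
    gcn_mut = file.path(dir, "gcn_mut.graphml"),
    edges_wt = file.path(dir, "edges_wt.tsv"),
    edges_mut = file.path(dir, "edges_mut.tsv"),
    comparison = file.path(dir, "gcn_comparison.tsv"),
    volcano = file.path(dir, "volcano.tsv"),
    stability = file.path(dir, "stability.tsv")
  )
  override <- list(...)
  paths[names(override)] <- override
  structure(list(dir = dir, paths = paths, alpha = alpha,
                 fc_threshold = fc_threshold, min_cluster = min_cluster,
                 correlation_kind = correlation_kind, seed = as.integer(seed),
                 log2_transform = log2_transform, preset = preset,
                 subsample_fraction = subsample_fraction,
                 subsample_repeats = subsample_repeats),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s'; run %s first", path, producer))
  }
  path
}

write_manifest <- function(config, stage, inputs, outputs, params = list()) {
  # paths are stored relative to the artifact directory so a run is
  # byte-identical wherever it lives
  rel <- function(p) lapply(p, function(x) {
    sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", config$dir), "/?"), "", x)
  })
  manifest <- list(
    stage = stage,
    package = "pairsurv",
    version = as.character(utils::packageVersion("pairsurv")),
    seed = config$seed,
    inputs = rel(inputs), outputs = rel(outputs),
    params = c(list(alpha = config$alpha, correlation_kind = config$correlation_kind,
                    log2_transform = config$log2_transform), params)
  )
  path <- file.path(config$dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

# shared loader for stages downstream of simulate
load_cohort_artifacts <- function(config, need_clinical = TRUE) {
  p <- config$paths
  require_artifact(p$expression, "pipeline_simulate()")
  require_artifact(p$reference, "pipeline_simulate()")
  genes <- if (file.exists(p$genes)) read_gene_list(p$genes) else NULL
  expr <- read_expression(p$expression, gene_list = genes,
                          log2_transform = config$log2_transform)
  ref <- read_expression(p$reference, gene_list = genes,
                         log2_transform = config$log2_transform)
  clinical <- NULL
  if (need_clinical) {
    require_artifact(p$clinical, "pipeline_simulate()")
    clinical <- read_clinical(p$clinical)
  }
  list(expr = expr, ref = ref, clinical = clinical)
}

#' Pipeline stage: generate a synthetic cohort
#'
#' Writes the benchmark cohort of `config$preset` (expression, reference
#' panel, clinical table, gene list, truth file) into `config$dir`.
#'
#' @param config A `run_config`.
#' @return The `synthetic_cohort`, invisibly.
#' @export
pipeline_simulate <- function(config) {
  cohort <- make_benchmark_cohort(config$preset, seed = config$seed)
  write_cohort(cohort, config$dir)
  write_manifest(config, "simulate", inputs = list(),
                 outputs = as.list(config$paths[c("expression", "reference",
                                                  "clinical", "genes")]),
                 params = list(preset = config$preset))
  invisible(cohort)
}

#' Pipeline stage: delta-PCC matrices and pair selection per group
#'
#' Builds the patients-by-pairs delta-PCC matrix against the reference
#' panel for each TP53 group, applies the three selection criteria and
#' the average-delta filter, and writes each group's matrix with its
#' selection sidecar.
#'
#' @param config A `run_config`.
#' @return A list with both groups' `delta_pcc` objects and selections,
#'   invisibly.
#' @export
pipeline_select <- function(config) {
  art <- load_cohort_artifacts(config)
  groups <- split_cohort(art$clinical)
  pairs <- all_gene_pairs(intersect(rownames(art$expr), rownames(art$ref)))

  run_group <- function(ids, label, out_path) {
    ids <- intersect(ids, colnames(art$expr))
    delta <- build_delta_matrix(art$ref, art$expr[, ids, drop = FALSE],
                                pairs = pairs, method = config$correlation_kind,
                                group_label = label)
    sel <- select_pairs(delta, alpha = config$alpha)
    sel <- average_delta_filter(delta, sel)
    write_delta_matrix(delta, out_path, selection = sel)
    list(delta = delta, selection = sel)
  }
  wt <- run_group(groups$wt_ids, "wtTP53", config$paths$delta_wt)
  mut <- run_group(groups$mut_ids, "mTP53", config$paths$delta_mut)
  write_manifest(config, "select",
                 inputs = as.list(config$paths[c("expression", "reference", "clinical")]),
                 outputs = as.list(config$paths[c("delta_wt", "delta_mut")]),
                 params = list(n_pairs = nrow(pairs),
                               n_retained_wt = sum(wt$selection$retained),
                               n_retained_mut = sum(mut$selection$retained)))
  invisible(list(wt = wt, mut = mut))
}

#' Pipeline stage: per-pair survival ranking per group
#'
#' Reads each group's delta matrix and selection, derives survival
#' records, ranks the retained pairs (stratify, log-rank, BH within the
#' group, Cox), and writes one result table per group in the headline
#' column layout.
#'
#' @param config A `run_config`.
#' @return A list with both groups' `pair_survival` tables, invisibly.
#' @export
pipeline_survival <- function(config) {
  p <- config$paths
  require_artifact(p$delta_wt, "pipeline_select()")
  require_artifact(p$delta_mut, "pipeline_select()")
  require_artifact(p$clinical, "pipeline_simulate()")
  surv <- derive_survival(read_clinical(p$clinical))

  run_group <- function(delta_path, out_path) {
    delta <- read_delta_matrix(delta_path)
    sel <- delta$selection
    if (is.null(sel)) abort(paste0("no selection sidecar in ", delta_path,
                                   "; run pipeline_select() first"))
    rk <- rank_pairs(delta, surv, pairs = sel, min_cluster = config$min_cluster)
    write_pair_table(rk, out_path)
    rk
  }
  wt <- run_group(p$delta_wt, p$pairs_wt)
  mut <- run_group(p$delta_mut, p$pairs_mut)
  write_manifest(config, "survival",
                 inputs = as.list(p[c("delta_wt", "delta_mut", "clinical")]),
                 outputs = as.list(p[c("pairs_wt", "pairs_mut")]),
                 params = list(min_cluster = config$min_cluster,
                               n_tested_wt = nrow(wt), n_tested_mut = nrow(mut)))
  invisible(list(wt = wt, mut = mut))
}

#' Pipeline stage: enriched GCN per group
#'
#' Builds each group's prognostic-information-enriched correlation network
#' over its retained pairs and writes GraphML plus edge-list TSV.
#'
#' @param config A `run_config`.
#' @return A list with both `gcn` objects, invisibly.
#' @export
pipeline_gcn <- function(config) {
  p <- config$paths
  require_artifact(p$delta_wt, "pipeline_select()")
  require_artifact(p$delta_mut, "pipeline_select()")
  art <- load_cohort_artifacts(config)
  surv <- derive_survival(art$clinical)
  groups <- split_cohort(art$clinical)

  run_group <- function(delta_path, ids, label, graphml, edgelist) {
    delta <- read_delta_matrix(delta_path)
    sel <- delta$selection
    if (is.null(sel)) abort(paste0("no selection sidecar in ", delta_path,
                                   "; run pipeline_select() first"))
    ids <- intersect(ids, colnames(art$expr))
    gcn <- build_gcn(art$expr[, ids, drop = FALSE], sel, surv,
                     alpha = config$alpha, method = config$correlation_kind,
                     group_label = label)
    export_graphml(gcn, graphml)
    export_edgelist(gcn, edgelist)
    gcn
  }
  wt <- run_group(p$delta_wt, groups$wt_ids, "wtTP53", p$gcn_wt, p$edges_wt)
  mut <- run_group(p$delta_mut, groups$mut_ids, "mTP53", p$gcn_mut, p$edges_mut)
  write_manifest(config, "gcn",
                 inputs = as.list(p[c("delta_wt", "delta_mut", "expression", "clinical")]),
                 outputs = as.list(p[c("gcn_wt", "gcn_mut", "edges_wt", "edges_mut")]),
                 params = list(n_edges_wt = nrow(wt$edges), n_edges_mut = nrow(mut$edges)))
  invisible(list(wt = wt, mut = mut))
}

#' Pipeline stage: compare the two groups' GCNs
#'
#' @param config A `run_config`.
#' @return The `gcn_comparison`, invisibly.
#' @export
pipeline_compare <- function(config) {
  p <- config$paths
  require_artifact(p$gcn_wt, "pipeline_gcn()")
  require_artifact(p$gcn_mut, "pipeline_gcn()")
  cmp <- compare_gcns(import_graphml(p$gcn_wt), import_graphml(p$gcn_mut))
  cmp$edges %>%
    mutate(across(c("weight_a", "weight_b", "p_a", "p_b"),
                  ~ifelse(is.na(.x), "", format_full(.x)))) %>%
    readr::write_tsv(p$comparison, progress = FALSE)
  jsonlite::write_json(as.list(cmp$counts), paste0(p$comparison, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "compare",
                 inputs = as.list(p[c("gcn_wt", "gcn_mut")]),
                 outputs = list(comparison = p$comparison),
                 params = as.list(cmp$counts))
  invisible(cmp)
}

#' Pipeline stage: two-group differential expression
#'
#' @param config A `run_config`.
#' @return The `de_result` tibble, invisibly.
#' @export
pipeline_diffexpr <- function(config) {
  art <- load_cohort_artifacts(config)
  groups <- split_cohort(art$clinical)
  de <- differential_expression(art$expr,
                                intersect(groups$wt_ids, colnames(art$expr)),
                                intersect(groups$mut_ids, colnames(art$expr)))
  write_volcano_table(de, config$paths$volcano)
  write_manifest(config, "diffexpr",
                 inputs = as.list(config$paths[c("expression", "clinical")]),
                 outputs = list(volcano = config$paths$volcano),
                 params = list(fc_threshold = config$fc_threshold,
                               n_de = nrow(de_filter(de, config$fc_threshold,
                                                     config$alpha))))
  invisible(de)
}

#' Pipeline stage: subsample robustness of the top pairs
#'
#' @param config A `run_config`.
#' @return A list with both groups' stability tibbles, invisibly.
#' @export
pipeline_robustness <- function(config) {
  p <- config$paths
  require_artifact(p$delta_wt, "pipeline_select()")
  require_artifact(p$delta_mut, "pipeline_select()")
  require_artifact(p$clinical, "pipeline_simulate()")
  surv <- derive_survival(read_clinical(p$clinical))

  run_group <- function(delta_path, offset) {
    delta <- read_delta_matrix(delta_path)
    suppressWarnings(robustness_subsample(
      delta, surv, pairs = delta$selection,
      fraction = config$subsample_fraction, repeats = config$subsample_repeats,
      seed = config$seed + offset, min_cluster = config$min_cluster))
  }
  wt <- run_group(p$delta_wt, 0)
  mut <- run_group(p$delta_mut, 100)
  out <- bind_rows(wt %>% mutate(group = "wtTP53"),
                   mut %>% mutate(group = "mTP53")) %>%
    select("group", everything())
  readr::write_tsv(out %>% mutate(across(c("full_adj_p", "full_cox_p"), format_full)),
                   p$stability, progress = FALSE)
  jsonlite::write_json(
    list(fraction = config$subsample_fraction, repeats = config$subsample_repeats,
         n_pairs_wt = nrow(wt), n_pairs_mut = nrow(mut)),
    paste0(p$stability, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(config, "robustness",
                 inputs = as.list(p[c("delta_wt", "delta_mut", "clinical")]),
                 outputs = list(stability = p$stability),
                 params = list(fraction = config$subsample_fraction,
                               repeats = config$subsample_repeats))
  invisible(list(wt = wt, mut = mut))
}
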