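#' Configuration for the end-to-end pipeline
#'
#' All thresholds default to the analysis' canonical values and are logged
#' verbatim into the run report: ANOVA FDR 0.05, Tukey adjusted p 0.01,
#' |log2FC| 2, silhouette cutoff 0.5 (pathways), per-miRNA context-score
#' quantile 0.05, centroid-template correlation floor 0.9, network edge
#' threshold |r| 0.7, k = 8 clusters.
#'
#' @param fdr ANOVA FDR gate.
#' @param tukey_alpha Tukey adjusted-p cutoff for transition calls.
#' @param lfc Absolute log2 fold-change cutoff.
#' @param silhouette Silhouette cutoff applied to pathway assignment.
#' @param target_quantile Per-miRNA context-score quantile.
#' @param min_match Centroid-template Pearson r floor.
#' @param min_abs_r Network edge |r| threshold.
#' @param sd_quantile SD-quantile gene filter level.
#' @param k Clusters for K-means.
#' @param n_restarts K-means restarts.
#' @param page_min_members Minimum matched members for PAGE.
#' @param n_top_pathways Pathways to rank per transition.
#' @param normalize_genes Quantile-normalize the gene matrix before
#'   filtering. Set to `FALSE` for inputs already on a normalized scale
#'   (e.g. the synthetic generator's matrices): re-normalizing a complete
#'   noise-free matrix injects rank-tie jitter into otherwise constant
#'   rows.
#' @param seed Integer seed governing all clustering.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr = 0.05, tukey_alpha = 0.01, lfc = 2,
                            silhouette = 0.5, target_quantile = 0.05,
                            min_match = 0.9, min_abs_r = 0.7,
                            sd_quantile = 0.25, k = 8L, n_restarts = 25L,
                            page_min_members = 3L, n_top_pathways = 2L,
                            normalize_genes = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(fdr > 0, fdr < 1, tukey_alpha > 0, tukey_alpha < 1, lfc >= 0,
            target_quantile > 0, target_quantile < 1,
            min_match >= -1, min_match <= 1, min_abs_r >= 0, min_abs_r <= 1,
            sd_quantile >= 0, sd_quantile < 1, k >= 2)
  structure(cfg, class = "pipeline_config")
}

#' Run the full progression-integromics pipeline
#'
#' Executes the complete workflow on in-memory inputs: miRNA zero-variance
#' filter, per-feature ANOVA + BH-FDR, Tukey HSD, transition attribution and
#' Venn partition; gene quantile normalization, SD-quantile filter and the
#' same inference; template mapping of significant miRNAs (standard
#' orientation) and genes (reversed); PAGE pathway scoring and
#' silhouette-filtered pathway mapping; context-score target filtering,
#' miRNA-mRNA integration and target-pathway derivation; top-pathway ranking
#' per transition; and correlation-network construction. Deterministic given
#' the config seed.
#'
#' @param mirna,gene Expression matrices (log2 scale) or paths to TSV files.
#' @param design [stage_design()] covering both matrices.
#' @param gene_sets List of [gene_set()]s or a GMT path.
#' @param targets Target-prediction data frame or TSV path.
#' @param config [pipeline_config()].
#' @param outdir Optional directory; when given, all intermediate tables,
#'   the network files and a JSON report are written there.
#' @return List of class `pipeline_result` with elements `report` (all
#'   counts), `config`, and the intermediates (`mirna_stats`,
#'   `mirna_calls`, `mirna_assignment`, `gene_stats`, `gene_assignment`,
#'   `pathway_scores`, `pathway_assignment`, `triples`, `target_pathways`,
#'   `top_pathways`, `network`, ...).
#' @export
run_pipeline <- function(mirna, gene, design, gene_sets, targets,
                         config = pipeline_config(), outdir = NULL) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (is.character(mirna)) mirna <- read_expression_matrix(mirna, "miRNA")
  if (is.character(gene)) gene <- read_expression_matrix(gene, "gene")
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(targets)) targets <- read_target_predictions(targets)
  cfg <- config

  ## miRNA arm
  mi_filt <- step("mirna_filter", remove_zero_variance(mirna))
  mi <- mi_filt$matrix
  mi_stats <- step("mirna_anova", suppressWarnings(anova_per_feature(mi, design)))
  mi_pairs <- step("mirna_tukey", suppressWarnings(tukey_hsd(mi, design)))
  mi_calls <- step("mirna_transitions", attribute_transitions(
    mi_pairs, mi_stats, design, lfc_threshold = cfg$lfc,
    alpha = cfg$tukey_alpha, anova_q_threshold = cfg$fdr))
  tr_labels <- adjacent_transitions(design)$label
  mi_venn <- venn_partition(mi_calls, transitions = tr_labels)
  mi_sig <- mi_stats$feature[mi_stats$q < cfg$fdr]
  mi_assign <- step("mirna_patterns", assign_patterns(
    mi[mi_sig, , drop = FALSE], design, k = cfg$k, seed = cfg$seed,
    n_restarts = cfg$n_restarts, min_match = cfg$min_match))

  ## gene arm
  ge_norm <- if (cfg$normalize_genes)
    step("gene_normalize", quantile_normalize(gene)) else gene
  ge_filt <- step("gene_filter", sd_quantile_filter(ge_norm, cfg$sd_quantile))
  ge <- ge_filt$matrix
  ge_stats <- step("gene_anova", suppressWarnings(anova_per_feature(ge, design)))
  ge_sig <- ge_stats$feature[ge_stats$q < cfg$fdr]
  ge_assign <- step("gene_patterns", assign_patterns(
    ge[ge_sig, , drop = FALSE], design, k = cfg$k, seed = cfg$seed + 1L,
    n_restarts = cfg$n_restarts, min_match = cfg$min_match, reverse = TRUE))

  ## pathway arm
  pw_scores <- step("page", page_scores(ge, gene_sets, cfg$page_min_members))
  pw_assign <- step("pathway_patterns", assign_patterns(
    pw_scores, design, k = cfg$k, seed = cfg$seed + 2L,
    n_restarts = cfg$n_restarts, min_match = cfg$min_match, reverse = TRUE,
    silhouette_cutoff = cfg$silhouette))

  ## integration
  targ_filt <- step("target_filter", filter_targets_by_context_score(
    targets, quantile = cfg$target_quantile))
  triples <- step("integration", integrate_mirna_mrna(
    mi_assign, ge_assign, targ_filt))
  triples_pw <- step("target_pathways", derive_target_pathways(
    triples, pw_assign, gene_sets))
  top_pw <- step("pathway_ranking", do.call(rbind, lapply(tr_labels, function(tl)
    rank_top_pathways(pw_scores, design, tl, n_top = cfg$n_top_pathways,
                      lfc = cfg$lfc, alpha = cfg$tukey_alpha))))

  ## network
  net <- step("network", suppressWarnings(build_network(
    triples_pw, mi, ge, pw_scores, min_abs_r = cfg$min_abs_r)))

  group_counts <- function(asg) {
    tab <- table(factor(asg$template, levels = paste0("G", 1:8)))
    as.list(setNames(as.integer(tab), names(tab)))
  }
  report <- list(
    mirna = list(n_input = mi_filt$report$n_input,
                 n_zero_variance = mi_filt$report$n_removed,
                 n_retained = mi_filt$report$n_retained,
                 n_significant = length(mi_sig),
                 n_assigned = sum(!is.na(mi_assign$template)),
                 n_unassigned = sum(is.na(mi_assign$template)),
                 group_sizes = group_counts(mi_assign),
                 n_transition_altered = length(unique(mi_calls$feature)),
                 transition_counts = as.list(table(mi_calls$transition)),
                 venn = as.list(mi_venn)),
    gene = list(n_input = ge_filt$report$n_input,
                n_removed_sd_filter = ge_filt$report$n_removed,
                n_retained = ge_filt$report$n_retained,
                n_significant = length(ge_sig),
                n_assigned = sum(!is.na(ge_assign$template)),
                group_sizes = group_counts(ge_assign)),
    pathway = list(n_sets_scored = nrow(pw_scores),
                   n_assigned = sum(!is.na(pw_assign$template)),
                   n_target_pathways = length(attr(triples_pw, "target_pathways"))),
    integration = list(n_predictions_in = nrow(targets),
                       n_predictions_filtered = nrow(targ_filt),
                       n_integrated_pairs = nrow(unique(triples[c("mirna", "gene")])),
                       n_integrated_genes = length(unique(triples$gene))),
    top_pathways = if (!is.null(top_pw)) split(top_pw$pathway, top_pw$transition),
    network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges)),
    thresholds = unclass(cfg))

  result <- structure(list(
    report = report, config = cfg,
    mirna_matrix = mi, mirna_stats = mi_stats, mirna_pairwise = mi_pairs,
    mirna_calls = mi_calls, mirna_assignment = mi_assign,
    gene_matrix = ge, gene_stats = ge_stats, gene_assignment = ge_assign,
    pathway_scores = pw_scores, pathway_assignment = pw_assign,
    triples = triples_pw,
    target_pathways = attr(triples_pw, "target_pathways"),
    top_pathways = top_pw, network = net), class = "pipeline_result")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_expression_matrix(mi, file.path(outdir, "mirna_filtered.tsv"))
    write_expression_matrix(ge, file.path(outdir, "gene_filtered.tsv"))
    write_expression_matrix(pw_scores, file.path(outdir, "pathway_scores.tsv"),
                            id_column = "pathway")
    for (nm in c("mirna_stats", "mirna_pairwise", "mirna_calls",
                 "mirna_assignment", "gene_stats", "gene_assignment",
                 "pathway_assignment", "triples", "top_pathways"))
      write.table(result[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_network_edgelist(net, file.path(outdir, "network"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Progression integromics pipeline\n")
  cat(sprintf("  miRNA: %d -> %d after zero-variance filter; %d significant; %d pattern-assigned\n",
              r$mirna$n_input, r$mirna$n_retained, r$mirna$n_significant,
              r$mirna$n_assigned))
  cat(sprintf("  genes: %d -> %d after SD filter; %d significant; %d pattern-assigned\n",
              r$gene$n_input, r$gene$n_retained, r$gene$n_significant,
              r$gene$n_assigned))
  cat(sprintf("  pathways: %d scored; %d assigned; %d target pathways\n",
              r$pathway$n_sets_scored, r$pathway$n_assigned,
              r$pathway$n_target_pathways))
  cat(sprintf("  integration: %d pairs over %d genes; network %d nodes / %d edges\n",
              r$integration$n_integrated_pairs,
              r$integration$n_integrated_genes,
              r$network$n_nodes, r$network$n_edges))
  invisible(x)
}
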