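#' Filter target predictions by context-score quantile
#'
#' For each miRNA with more than one prediction, keeps predictions whose
#' total context score lies at or below that miRNA's `quantile` quantile
#' (the most negative, strongest tail; ties at the cutoff are kept). miRNAs
#' with a single prediction are kept as-is. With `per_mirna = FALSE` a
#' single global cutoff over all scores is used instead.
#'
#' @param predictions Target-prediction data frame (see
#'   [read_target_predictions()]).
#' @param quantile Quantile in (0, 1); default the strict 5% cutoff.
#' @param per_mirna Apply the cutoff within each miRNA (default) or globally.
#' @return Filtered prediction data frame.
#' @export
filter_targets_by_context_score <- function(predictions, quantile = 0.05,
                                            per_mirna = TRUE) {
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1)
    stop("`quantile` must be a single value in (0, 1)")
  if (!nrow(predictions)) return(predictions)
  if (per_mirna) {
    keep <- unlist(lapply(split(seq_len(nrow(predictions)), predictions$mirna),
      function(idx) {
        if (length(idx) == 1L) return(idx)
        sc <- predictions$total_context_score[idx]
        idx[sc <= stats::quantile(sc, probs = quantile, type = 7)]
      }))
    out <- predictions[sort(keep), , drop = FALSE]
  } else {
    cutoff <- stats::quantile(predictions$total_context_score,
                              probs = quantile, type = 7)
    out <- predictions[predictions$total_context_score <= cutoff, ,
                       drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Representative miRNA per family
#'
#' Within each miRNA family, the miRNA whose best (lowest) total context
#' score is the lowest becomes the family representative; exact ties break
#' to the lexicographically first miRNA id.
#'
#' @param predictions Target-prediction data frame with `family` labels.
#' @return Named character vector, family -> representative miRNA.
#' @export
representative_mirna_per_family <- function(predictions) {
  if (!nrow(predictions)) return(setNames(character(0), character(0)))
  best <- stats::aggregate(total_context_score ~ mirna + family,
                           data = predictions, FUN = min)
  reps <- vapply(split(best, best$family), function(df) {
    df <- df[order(df$total_context_score, df$mirna), , drop = FALSE]
    df$mirna[1L]
  }, "")
  reps
}

#' Integrate miRNA and gene pattern groups through target predictions
#'
#' A (miRNA, gene) prediction becomes an integrated pair iff the miRNA is
#' assigned to some template Gk and the gene is assigned to Gk under the
#' gene-side (reversed-direction) template orientation, so the pair shares a
#' timing class with opposite directions of change.
#'
#' @param mirna_assignment `pattern_assignment` for miRNAs (standard
#'   orientation).
#' @param gene_assignment `pattern_assignment` for genes (assigned with
#'   `reverse = TRUE` templates).
#' @param predictions Filtered target-prediction data frame.
#' @return Data frame of integrated triples (pathway not yet filled):
#'   `mirna`, `gene`, `group`.
#' @export
integrate_mirna_mrna <- function(mirna_assignment, gene_assignment, predictions) {
  mg <- setNames(mirna_assignment$template, mirna_assignment$feature)
  gg <- setNames(gene_assignment$template, gene_assignment$feature)
  grp_m <- mg[predictions$mirna]
  grp_g <- gg[predictions$gene]
  keep <- !is.na(grp_m) & !is.na(grp_g) & grp_m == grp_g
  data.frame(mirna = predictions$mirna[keep], gene = predictions$gene[keep],
             group = unname(grp_m[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Derive target pathways by gene-membership overlap
#'
#' A pathway assigned to pattern group Gk becomes a target pathway iff it
#' shares at least one member with the integrated gene list of group Gk.
#' Triples whose gene belongs to such a pathway are expanded with the
#' pathway link; the full set of selected pathways is attached as the
#' `target_pathways` attribute.
#'
#' @param triples Output of [integrate_mirna_mrna()].
#' @param pathway_assignment `pattern_assignment` of PAGE pathway scores
#'   (silhouette-filtered).
#' @param gene_sets The gene-set list the pathways came from.
#' @return Data frame `mirna`, `gene`, `pathway` (NA where the gene belongs
#'   to no target pathway of its group), `group`; attribute
#'   `target_pathways`.
#' @export
derive_target_pathways <- function(triples, pathway_assignment, gene_sets) {
  members <- setNames(lapply(gene_sets, `[[`, "members"),
                      vapply(gene_sets, `[[`, "", "name"))
  pg <- pathway_assignment[!is.na(pathway_assignment$template), , drop = FALSE]
  selected <- character(0)
  rows <- list()
  for (i in seq_len(nrow(pg))) {
    pw <- pg$feature[i]; grp <- pg$template[i]
    genes_grp <- triples$gene[triples$group == grp]
    overlap <- intersect(members[[pw]], genes_grp)
    if (!length(overlap)) next
    selected <- c(selected, pw)
    hit <- triples$group == grp & triples$gene %in% overlap
    ex <- triples[hit, , drop = FALSE]
    ex$pathway <- pw
    rows[[length(rows) + 1L]] <- ex
  }
  linked <- if (length(rows)) do.call(rbind, rows) else
    cbind(triples[0, , drop = FALSE], pathway = character(0))
  lone_key <- !paste(triples$mirna, triples$gene) %in%
    paste(linked$mirna, linked$gene)
  lone <- triples[lone_key, , drop = FALSE]
  if (nrow(lone)) lone$pathway <- NA_character_
  out <- rbind(linked, lone)
  out <- out[, c("mirna", "gene", "pathway", "group")]
  rownames(out) <- NULL
  attr(out, "target_pathways") <- unique(selected)
  out
}

#' Rank the most altered pathways at a transition
#'
#' Reuses the Tukey HSD machinery on the pathway-score matrix: pathways
#' passing |score change| >= `lfc` and Tukey adjusted p < `alpha` at the
#' given adjacent transition are ranked by |change|, then adjusted p; the
#' top `n_top` are returned. An empty ranking means no pathway was
#' significantly dysregulated at that transition.
#'
#' @param pathway_scores Pathway x sample score matrix ([page_scores()]).
#' @param design [stage_design()].
#' @param transition Transition label, e.g. `"AT1->DCIS"`.
#' @param n_top Number of pathways to return.
#' @param lfc Absolute score-change cutoff.
#' @param alpha Tukey adjusted-p cutoff.
#' @return Data frame `pathway`, `transition`, `delta_score`, `p_adj`,
#'   `rank` (possibly zero rows).
#' @export
rank_top_pathways <- function(pathway_scores, design, transition, n_top = 2L,
                              lfc = 2, alpha = 0.01) {
  tr <- adjacent_transitions(design)
  if (!transition %in% tr$label)
    stop("unknown transition: ", transition, "; expected one of ",
         paste(tr$label, collapse = ", "))
  pw <- tukey_hsd(pathway_scores, design)
  key <- paste(pw$stage_a, pw$stage_b, sep = "->")
  cand <- pw[key == transition & abs(pw$mean_diff) >= lfc & pw$p_adj < alpha, ,
             drop = FALSE]
  cand <- cand[order(-abs(cand$mean_diff), cand$p_adj), , drop = FALSE]
  cand <- head(cand, n_top)
  data.frame(pathway = cand$feature, transition = rep(transition, nrow(cand)),
             delta_score = cand$mean_diff, p_adj = cand$p_adj,
             rank = seq_len(nrow(cand)), stringsAsFactors = FALSE,
             row.names = NULL)
}
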