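#' Build the miRNA-gene-pathway correlation network
#'
#' Nodes are the distinct miRNAs, genes and pathways appearing in the
#' integrated triples; edges are `targets` (miRNA -> gene) and `member_of`
#' (gene -> pathway) relations weighted by the Pearson correlation of the
#' two entities' per-sample profiles. Edges with |r| below `min_abs_r` are
#' dropped; edges whose endpoints have a constant profile (undefined r) are
#' omitted with a warning. Node direction (up/down) comes from the sign of
#' the entity's assigned template: miRNA groups G1..G4 rise, G5..G8 fall,
#' and genes/pathways carry the reversed orientation.
#'
#' @param triples Output of [derive_target_pathways()] (or
#'   [integrate_mirna_mrna()]; pathway links optional).
#' @param mirna_matrix,gene_matrix Expression matrices over the same samples.
#' @param pathway_scores Pathway score matrix over the same samples (may be
#'   NULL when triples carry no pathways).
#' @param min_abs_r Minimum |Pearson r| to keep an edge.
#' @return A `network_graph`: list with `nodes` (id, type, group, direction)
#'   and `edges` (source, target, weight, sign, relation) data frames.
#' @export
build_network <- function(triples, mirna_matrix, gene_matrix,
                          pathway_scores = NULL, min_abs_r = 0.7) {
  up_groups <- c("G1", "G2", "G3", "G4")
  profile <- function(id, type) {
    m <- switch(type, miRNA = mirna_matrix, gene = gene_matrix,
                pathway = pathway_scores)
    if (is.null(m) || !id %in% rownames(m)) return(NULL)
    as.numeric(as_plain_matrix(m)[id, ])
  }
  has_pw <- "pathway" %in% names(triples)
  nodes <- rbind(
    data.frame(id = triples$mirna, type = "miRNA", group = triples$group,
               stringsAsFactors = FALSE),
    data.frame(id = triples$gene, type = "gene", group = triples$group,
               stringsAsFactors = FALSE),
    if (has_pw && any(!is.na(triples$pathway)))
      data.frame(id = triples$pathway[!is.na(triples$pathway)],
                 type = "pathway",
                 group = triples$group[!is.na(triples$pathway)],
                 stringsAsFactors = FALSE))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes$direction <- ifelse(nodes$group %in% up_groups,
                            ifelse(nodes$type == "miRNA", "up", "down"),
                            ifelse(nodes$type == "miRNA", "down", "up"))
  rownames(nodes) <- NULL

  pairs <- unique(data.frame(source = triples$mirna, target = triples$gene,
                             relation = "targets", stringsAsFactors = FALSE))
  if (has_pw) {
    pw <- triples[!is.na(triples$pathway), , drop = FALSE]
    if (nrow(pw))
      pairs <- rbind(pairs, unique(data.frame(
        source = pw$gene, target = pw$pathway, relation = "member_of",
        stringsAsFactors = FALSE)))
  }
  type_of <- setNames(nodes$type, nodes$id)
  w <- numeric(nrow(pairs)); keep <- logical(nrow(pairs))
  n_const <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- profile(pairs$source[i], type_of[[pairs$source[i]]])
    b <- profile(pairs$target[i], type_of[[pairs$target[i]]])
    if (is.null(a) || is.null(b)) next
    if (sd(a) == 0 || sd(b) == 0) { n_const <- n_const + 1L; next }
    r <- cor(a, b)
    if (abs(r) >= min_abs_r) { w[i] <- r; keep[i] <- TRUE }
  }
  if (n_const) warning(n_const, " edge(s) omitted: constant profile, correlation undefined")
  edges <- data.frame(source = pairs$source[keep], target = pairs$target[keep],
                      weight = w[keep], sign = ifelse(w[keep] >= 0, 1L, -1L),
                      relation = pairs$relation[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(nodes = nodes, edges = edges), class = "network_graph")
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("network_graph: %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(names(table(x$nodes$type)), table(x$nodes$type),
                    sep = ":", collapse = ", "), nrow(x$edges)))
  invisible(x)
}

#' Hierarchical leaf order for heat-map rendering
#'
#' Agglomerative clustering with Ward linkage on the correlation
#' dissimilarity d = 1 - Pearson r between items; returns the dendrogram
#' leaf order. Constant items (undefined r) get d = 1 to every other item,
#' with a warning.
#'
#' @param m Numeric matrix.
#' @param axis `"rows"` (default) or `"columns"`.
#' @return Integer leaf order (named by item id) with the `hclust` object as
#'   attribute `hclust`.
#' @export
hierarchical_order <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- as_plain_matrix(m)
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2L) stop("need at least 2 items to order")
  sds <- apply(x, 1L, sd)
  r <- suppressWarnings(cor(t(x)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant item(s): dissimilarity set to 1")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  d <- 1 - r
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "ward.D")
  setNames(structure(hc$order, hclust = hc), rownames(x)[hc$order])
}
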