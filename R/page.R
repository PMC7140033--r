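#' PAGE pathway Z-scores
#'
#' Parametric analysis of gene set enrichment: for each sample column, with
#' mu and delta the mean and (n-1) SD of all gene values in that column, a
#' set with m matched members and member mean Sm scores
#' Z = (Sm - mu) * sqrt(m) / delta. Members absent from the matrix are
#' excluded from m; sets ending up with fewer than `min_members` matched
#' members are dropped (reported in the `dropped_sets` attribute).
#'
#' @param m Gene expression matrix (normalized log2 scale).
#' @param gene_sets List of [gene_set()] objects.
#' @param min_members Minimum matched members per set.
#' @return An [expression_matrix()] of kind `"pathway"` (sets x samples) with
#'   attribute `dropped_sets` (named integer vector of matched sizes of the
#'   dropped sets).
#' @export
page_scores <- function(m, gene_sets, min_members = 3L) {
  x <- as_plain_matrix(m)
  if (anyNA(x)) stop("missing values are not allowed in PAGE scoring")
  mu <- colMeans(x)
  delta <- apply(x, 2L, sd)
  if (any(delta == 0))
    stop("zero expression SD in column(s): ",
         paste(colnames(x)[delta == 0], collapse = ", "))
  genes <- rownames(x)
  matched <- lapply(gene_sets, function(s) intersect(s$members, genes))
  sizes <- lengths(matched)
  names(sizes) <- vapply(gene_sets, `[[`, "", "name")
  keep <- sizes >= min_members
  if (!any(keep)) stop("no gene set has >= ", min_members, " matched members")
  z <- vapply(which(keep), function(i) {
    sm <- colMeans(x[matched[[i]], , drop = FALSE])
    (sm - mu) * sqrt(sizes[i]) / delta
  }, numeric(ncol(x)))
  z <- t(matrix(z, nrow = ncol(x)))
  rownames(z) <- names(sizes)[keep]
  colnames(z) <- colnames(x)
  out <- expression_matrix(z, "pathway")
  attr(out, "dropped_sets") <- sizes[!keep]
  out
}
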