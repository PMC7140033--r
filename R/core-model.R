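#' Construct an expression matrix
#'
#' A thin S3 container around a numeric features x samples matrix of
#' log2-scale abundances, tagged with the kind of feature it holds.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @param kind One of `"miRNA"`, `"gene"`, `"pathway"`.
#' @return An `ExpressionMatrix` (a classed numeric matrix with a `kind`
#'   attribute).
#' @export
expression_matrix <- function(values, kind = c("miRNA", "gene", "pathway")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(colnames(values)) || (nrow(values) > 0 && is.null(rownames(values))))
    stop("`values` must have feature rownames and sample colnames")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  structure(values, kind = kind, class = c("ExpressionMatrix", class(values)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  y <- x
  attributes(y) <- attributes(x)[c("dim", "dimnames")]
  print(head(y[, seq_len(min(6L, ncol(y))), drop = FALSE], 6L), ...)
  invisible(x)
}

# Strip the class but keep dimnames; used before handing to matrix code that
# would otherwise dispatch.
as_plain_matrix <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

# Re-wrap a derived matrix with the kind of its parent (default: keep rows of
# a filtered matrix tagged as before).
rewrap <- function(values, template) {
  kind <- attr(template, "kind")
  if (is.null(kind)) return(values)
  expression_matrix(values, kind)
}

#' Describe the stage/replicate layout of the samples
#'
#' @param sample_id Character vector of sample ids.
#' @param stage Character or factor giving each sample's progression stage.
#' @param replicate Positive integer replicate index within stage.
#' @param stage_levels Ordered stage labels; defaults to the order of first
#'   appearance in `stage`.
#' @return A `StageDesign` data frame with columns `sample_id`, `stage`
#'   (factor with ordered levels), `replicate`.
#' @export
stage_design <- function(sample_id, stage, replicate,
                         stage_levels = unique(as.character(stage))) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample id(s) in design")
  stage <- factor(as.character(stage), levels = stage_levels)
  if (anyNA(stage)) stop("stage label outside `stage_levels`")
  if (nlevels(droplevels(stage)) < 2L)
    stop("a StageDesign needs at least 2 stages")
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate indices must be positive")
  structure(
    data.frame(sample_id = as.character(sample_id), stage = stage,
               replicate = replicate, stringsAsFactors = FALSE),
    class = c("StageDesign", "data.frame"))
}

#' Default four-stage triplicate design
#'
#' The MCF10A-panel layout: stages P, AT1, DCIS, CA1D with three replicates
#' each, samples named `<stage>_<replicate>`.
#'
#' @param stages Ordered stage labels.
#' @param n_rep Replicates per stage.
#' @return A [stage_design()] data frame.
#' @export
default_stage_design <- function(stages = c("P", "AT1", "DCIS", "CA1D"),
                                 n_rep = 3L) {
  stage <- rep(stages, each = n_rep)
  rep_i <- rep(seq_len(n_rep), times = length(stages))
  stage_design(paste(stage, rep_i, sep = "_"), stage, rep_i,
               stage_levels = stages)
}

# Check that every column of `m` has exactly one design row; returns the
# design subset in column order.
match_design <- function(m, design) {
  idx <- match(colnames(m), design$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from design: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  design[idx, , drop = FALSE]
}

#' Per-stage mean expression
#'
#' Collapses a features x samples matrix to a features x stages matrix of
#' within-stage means, in stage order.
#'
#' @param m Expression matrix.
#' @param design [stage_design()] covering the columns of `m`.
#' @return Numeric matrix, one column per stage level present.
#' @export
stage_means <- function(m, design) {
  d <- match_design(m, design)
  stages <- levels(droplevels(d$stage))
  out <- matrix(NA_real_, nrow(m), length(stages),
                dimnames = list(rownames(m), stages))
  for (s in stages) out[, s] <- rowMeans(m[, d$stage == s, drop = FALSE])
  out
}

# Adjacent-stage transitions of a design, labelled "A->B".
adjacent_transitions <- function(design) {
  st <- levels(droplevels(design$stage))
  data.frame(from = st[-length(st)], to = st[-1L],
             label = paste(st[-length(st)], st[-1L], sep = "->"),
             stringsAsFactors = FALSE)
}

#' Construct a gene set
#'
#' @param name Set name (unique within a collection).
#' @param members Character vector of gene ids; duplicates are dropped.
#' @param collection Collection label (e.g. `"C2"`).
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, members, collection = "") {
  members <- unique(as.character(members))
  if (!length(members)) stop("gene set ", name, " has no members")
  structure(list(name = as.character(name), collection = as.character(collection),
                 members = members), class = "gene_set")
}
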