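#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values q_(i) = min_{j>=i}(p_(j) * n / j), capped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# Pooled within-stage statistics for one-way ANOVA, vectorized over rows.
# Returns group means, group sizes, SSB, SSW, dfs.
.oneway_components <- function(m, design) {
  d <- match_design(m, design)
  if (anyNA(m)) stop("missing values are not allowed in inferential operations")
  stages <- levels(droplevels(d$stage))
  n_per <- vapply(stages, function(s) sum(d$stage == s), 0L)
  if (any(n_per < 2L))
    stop("every stage needs >= 2 replicates; offending stage(s): ",
         paste(stages[n_per < 2L], collapse = ", "))
  x <- as_plain_matrix(m)
  gm <- stage_means(m, design)                       # features x stages
  grand <- rowMeans(x)
  ssb <- as.vector((gm - grand)^2 %*% n_per)
  ssw <- numeric(nrow(x))
  for (s in stages) {
    cols <- d$stage == s
    ssw <- ssw + rowSums((x[, cols, drop = FALSE] - gm[, s])^2)
  }
  list(group_means = gm, n_per = n_per, ssb = ssb, ssw = ssw,
       df_b = length(stages) - 1L, df_w = ncol(x) - length(stages),
       stages = stages)
}

#' Per-feature one-way ANOVA across stages
#'
#' Fixed-effects one-way ANOVA per row with stage as the factor;
#' F = (SSB/df_b) / (SSW/df_w); BH-FDR q-values over all rows. Features with
#' zero within-stage variance get the boundary values F = Inf, p = 0 when
#' their stage means differ (with a warning) and F = 0, p = 1 when they do
#' not, so zero-noise data flows through.
#'
#' @param m Expression matrix (complete; every stage with >= 2 replicates).
#' @param design [stage_design()].
#' @param tol Sums-of-squares tolerance for the degenerate branches.
#' @return Data frame: `feature`, `F`, `df_between`, `df_within`, `p`, `q`.
#' @export
anova_per_feature <- function(m, design, tol = 1e-12) {
  cmp <- .oneway_components(m, design)
  f <- (cmp$ssb / cmp$df_b) / (cmp$ssw / cmp$df_w)
  p <- pf(f, cmp$df_b, cmp$df_w, lower.tail = FALSE)
  deg <- cmp$ssw <= tol
  if (any(deg & cmp$ssb > tol)) {
    warning(sum(deg & cmp$ssb > tol),
            " feature(s) with zero within-stage variance and unequal means; p set to 0")
    f[deg & cmp$ssb > tol] <- Inf
    p[deg & cmp$ssb > tol] <- 0
  }
  flat <- deg & cmp$ssb <= tol
  f[flat] <- 0
  p[flat] <- 1
  data.frame(feature = rownames(m), F = f, df_between = cmp$df_b,
             df_within = cmp$df_w, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Upper tail of the studentized range distribution
#'
#' P(Q >= q) for the range of k standard-normal group means studentized by an
#' independent chi-square SD estimate on `df` degrees of freedom.
#'
#' @param q Non-negative quantile(s).
#' @param k Number of groups (>= 2).
#' @param df Within-group degrees of freedom (>= 1).
#' @return Upper-tail probability.
#' @export
studentized_range_sf <- function(q, k, df) {
  if (k < 2 || df < 1) stop("need k >= 2 and df >= 1")
  if (any(q < 0)) stop("q must be non-negative")
  ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
}

#' Tukey HSD post-hoc contrasts per feature
#'
#' All stage pairs; mean differences are later-stage minus earlier-stage in
#' design order, so their sign is the direction of change along progression.
#' The studentized range statistic uses the Tukey-Kramer denominator
#' sqrt(MSE/2 * (1/n_i + 1/n_j)), which reduces to sqrt(MSE/n) for balanced
#' stages. Zero-MSE features get boundary p-values (0 if the pair's means
#' differ, 1 if not) with a warning.
#'
#' @param m Expression matrix.
#' @param design [stage_design()].
#' @param tol Tolerance for the zero-MSE branch.
#' @return Data frame: `feature`, `stage_a`, `stage_b`, `mean_diff`,
#'   `q_stat`, `p_adj`, `log2fc` (= `mean_diff`; the matrix is log2 scale).
#' @export
tukey_hsd <- function(m, design, tol = 1e-12) {
  cmp <- .oneway_components(m, design)
  mse <- cmp$ssw / cmp$df_w
  k <- length(cmp$stages)
  pairs <- combn(cmp$stages, 2L)
  out <- vector("list", ncol(pairs))
  warned <- FALSE
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    diff <- cmp$group_means[, b] - cmp$group_means[, a]
    se <- sqrt(mse / 2 * (1 / cmp$n_per[[a]] + 1 / cmp$n_per[[b]]))
    qs <- abs(diff) / se
    p <- studentized_range_sf(ifelse(is.finite(qs), qs, 0), k, cmp$df_w)
    deg <- mse <= tol
    if (any(deg)) {
      warned <- TRUE
      hit <- deg & abs(diff) > tol
      qs[hit] <- Inf; p[hit] <- 0
      qs[deg & !hit] <- 0; p[deg & !hit] <- 1
    }
    out[[j]] <- data.frame(feature = rownames(m), stage_a = a, stage_b = b,
                           mean_diff = unname(diff), q_stat = unname(qs),
                           p_adj = unname(p), log2fc = unname(diff),
                           stringsAsFactors = FALSE)
  }
  if (warned) warning("zero-MSE feature(s): boundary Tukey p-values assigned")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Log2 fold change between two stages
#'
#' @param m Log2-scale expression matrix.
#' @param design [stage_design()].
#' @param stage_a,stage_b Stage labels; the result is mean(`stage_b`) -
#'   mean(`stage_a`) per feature.
#' @return Named numeric vector.
#' @export
log_fold_change <- function(m, design, stage_a, stage_b) {
  gm <- stage_means(m, design)
  for (s in c(stage_a, stage_b))
    if (!s %in% colnames(gm)) stop("unknown stage: ", s)
  gm[, stage_b] - gm[, stage_a]
}

#' Attribute significant changes to adjacent stage transitions
#'
#' Restricted to features passing the ANOVA FDR gate, a feature is called at
#' an adjacent transition iff |log2FC| >= `lfc_threshold` and the Tukey
#' adjusted p for that pair is < `alpha`; direction follows the sign of the
#' mean difference.
#'
#' @param pairwise Output of [tukey_hsd()].
#' @param anova_stats Output of [anova_per_feature()].
#' @param design [stage_design()] (defines the adjacent transitions).
#' @param lfc_threshold Absolute log2 fold-change cutoff.
#' @param alpha Tukey adjusted-p cutoff.
#' @param anova_q_threshold ANOVA FDR gate.
#' @return Data frame: `feature`, `transition` (e.g. `"P->AT1"`),
#'   `direction` (`"up"`/`"down"`).
#' @export
attribute_transitions <- function(pairwise, anova_stats, design,
                                  lfc_threshold = 2, alpha = 0.01,
                                  anova_q_threshold = 0.05) {
  sig <- anova_stats$feature[anova_stats$q < anova_q_threshold]
  tr <- adjacent_transitions(design)
  key <- paste(pairwise$stage_a, pairwise$stage_b, sep = "->")
  hit <- pairwise$feature %in% sig & key %in% tr$label &
    abs(pairwise$log2fc) >= lfc_threshold & pairwise$p_adj < alpha
  calls <- pairwise[hit, , drop = FALSE]
  data.frame(feature = calls$feature,
             transition = paste(calls$stage_a, calls$stage_b, sep = "->"),
             direction = ifelse(calls$mean_diff > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition transition calls into Venn regions
#'
#' For the three adjacent transitions, counts features in each of the 7
#' regions of the 3-set Venn diagram (which transitions a feature was called
#' at, regardless of direction). Counts sum to the number of called features.
#'
#' @param calls Output of [attribute_transitions()].
#' @param transitions Character vector of the three transition labels, in
#'   order; defaults to those present in `calls`.
#' @return Named integer vector over the 7 non-empty membership patterns,
#'   named by the transitions joined with `" & "`.
#' @export
venn_partition <- function(calls, transitions = NULL) {
  if (is.null(transitions)) transitions <- unique(calls$transition)
  membership <- lapply(split(calls$transition, calls$feature),
                       function(tr) sort(match(unique(tr), transitions)))
  combos <- unlist(lapply(seq_along(transitions), function(sz)
    combn(seq_along(transitions), sz, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(combos, function(cb)
    sum(vapply(membership, function(mb) identical(mb, cb), TRUE)), 0L)
  names(counts) <- vapply(combos, function(cb)
    paste(transitions[cb], collapse = " & "), "")
  counts
}
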