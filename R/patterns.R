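#' The eight progression-pattern templates
#'
#' Canonical stage-level shapes over the four ordered stages: G1 early and
#' continuous increase (0,1,2,3); G2 early increase then plateau (0,1,1,1);
#' G3 delayed increase (0,0,1,1); G4 late increase (0,0,0,1); G5..G8 their
#' sign mirrors (late/delayed/early decrease, early continuous decrease).
#' With `reverse = TRUE` the shapes are negated, giving the gene-side
#' orientation in which group Gk pairs with a miRNA of group Gk acting in
#' the opposite direction (gene G1 = continuous decrease, etc.).
#'
#' @param reverse Negate the shapes (gene/pathway orientation).
#' @return 8 x 4 numeric matrix, rownames G1..G8.
#' @export
progression_templates <- function(reverse = FALSE) {
  shapes <- rbind(
    G1 = c(0, 1, 2, 3),
    G2 = c(0, 1, 1, 1),
    G3 = c(0, 0, 1, 1),
    G4 = c(0, 0, 0, 1),
    G5 = c(0, 0, 0, -1),
    G6 = c(0, 0, -1, -1),
    G7 = c(0, -1, -1, -1),
    G8 = c(0, -1, -2, -3))
  colnames(shapes) <- c("S1", "S2", "S3", "S4")
  if (reverse) -shapes else shapes
}

#' Row-standardize a matrix
#'
#' Z-scores each row; zero-SD rows become all-zero (flat) vectors.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape.
#' @export
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' K-means clustering of stage-profile vectors
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_restarts` runs by
#' total within-cluster sum of squares; deterministic given `seed`.
#'
#' @param x Numeric matrix (rows = items, typically standardized per-stage
#'   means).
#' @param k Number of clusters (>= 2, <= nrow(x)).
#' @param seed Integer RNG seed (required; recorded in the result).
#' @param n_restarts Independent restarts.
#' @param iter_max Lloyd iteration cap per restart.
#' @return List of class `cluster_result`: `labels` (named integer),
#'   `centroids` (k x ncol), `inertia`, `k`, `seed`.
#' @export
kmeans_cluster <- function(x, k = 8L, seed, n_restarts = 25L, iter_max = 100L) {
  if (missing(seed)) stop("`seed` is required for reproducible clustering")
  if (k > nrow(x)) stop("k exceeds the number of items")
  if (k < 2L) stop("k must be >= 2")
  x <- as_plain_matrix(x)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- .kmeanspp_init(x, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = centers, algorithm = "Lloyd",
                                iter.max = iter_max)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  structure(list(labels = setNames(best$cluster, rownames(x)),
                 centroids = best$centers, inertia = best$tot.withinss,
                 k = k, seed = seed), class = "cluster_result")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[idx[1L], ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) idx[j] <- sample.int(n, 1L)
    else idx[j] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, colSums((t(x) - x[idx[j], ])^2))
  }
  x[idx, , drop = FALSE] + 0  # copy
}

#' Assign K-means clusters to progression templates
#'
#' Each cluster is matched to the template maximizing the Pearson
#' correlation between its centroid and the template shape; every member
#' feature inherits its cluster's template. Clusters whose best correlation
#' is below `min_match`, is undefined (flat centroid), or is tied between
#' templates are left unassigned with a reason code. If `data` is supplied,
#' per-feature silhouette widths over the clustering are attached.
#'
#' @param clusters A `cluster_result` from [kmeans_cluster()].
#' @param templates Template matrix from [progression_templates()].
#' @param min_match Minimum Pearson r between centroid and template.
#' @param data Optional matrix the clustering was run on (for silhouettes).
#' @return Data frame of class `pattern_assignment`: `feature`, `cluster`,
#'   `template` (G1..G8 or NA), `match_score`, `silhouette`, `reason`.
#' @export
assign_clusters_to_templates <- function(clusters, templates = progression_templates(),
                                         min_match = 0.9, data = NULL) {
  k <- clusters$k
  tmpl <- rep(NA_character_, k)
  score <- rep(NA_real_, k)
  reason <- rep(NA_character_, k)
  for (cl in seq_len(k)) {
    cen <- clusters$centroids[cl, ]
    if (sd(cen) == 0) { reason[cl] <- "flat_centroid"; next }
    r <- apply(templates, 1L, function(sh) cor(cen, sh))
    best <- which.max(r)
    score[cl] <- r[best]
    if (sum(abs(r - r[best]) < 1e-12) > 1L) { reason[cl] <- "ambiguous_match"; next }
    if (r[best] < min_match) { reason[cl] <- "low_match"; next }
    tmpl[cl] <- rownames(templates)[best]
  }
  lab <- clusters$labels
  sil <- rep(NA_real_, length(lab))
  if (!is.null(data) && k >= 2L)
    sil <- silhouette_scores(as_plain_matrix(data)[names(lab), , drop = FALSE], lab)
  structure(
    data.frame(feature = names(lab), cluster = unname(lab),
               template = tmpl[lab], match_score = score[lab],
               silhouette = unname(sil), reason = reason[lab],
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("pattern_assignment", "data.frame"))
}

#' Silhouette widths
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean Euclidean
#' distance to the other members of i's cluster and b(i) the smallest mean
#' distance to any other cluster. Members of singleton clusters get 0.
#'
#' @param x Numeric matrix of items (rows).
#' @param labels Integer cluster label per row.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_scores <- function(x, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least 2 clusters")
  if (length(labels) != nrow(x)) stop("one label per row required")
  d <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a <- mean(d[i, labels == own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), own), function(cl)
      mean(d[i, labels == cl]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  setNames(s, rownames(x))
}

#' Unassign items with sub-threshold silhouette
#'
#' Items whose silhouette width falls below `threshold` lose their template
#' (reason `"low_silhouette"`); all others are unchanged. Used with the 0.5
#' cutoff to drop improperly clustered pathways.
#'
#' @param assignment A `pattern_assignment` with silhouettes attached.
#' @param threshold Silhouette cutoff.
#' @return The filtered `pattern_assignment`.
#' @export
filter_by_silhouette <- function(assignment, threshold = 0.5) {
  if (all(is.na(assignment$silhouette)))
    stop("assignment carries no silhouette scores; pass `data` to assign_clusters_to_templates()")
  hit <- !is.na(assignment$silhouette) & assignment$silhouette < threshold &
    !is.na(assignment$template)
  assignment$template[hit] <- NA_character_
  assignment$reason[hit] <- "low_silhouette"
  assignment
}

#' Map features onto the eight progression templates
#'
#' Convenience wrapper for the full pattern-mapping step: per-stage means,
#' row standardization, K-means, template matching, and optional silhouette
#' filtering.
#'
#' @param m Expression matrix (typically significant features only).
#' @param design [stage_design()].
#' @param k Number of clusters.
#' @param seed RNG seed for K-means.
#' @param n_restarts K-means restarts.
#' @param min_match Centroid-template correlation floor.
#' @param reverse Use gene-side (negated) template orientation.
#' @param silhouette_cutoff If non-NULL, apply [filter_by_silhouette()].
#' @return A `pattern_assignment` data frame.
#' @export
assign_patterns <- function(m, design, k = 8L, seed, n_restarts = 25L,
                            min_match = 0.9, reverse = FALSE,
                            silhouette_cutoff = NULL) {
  sm <- standardize_rows(stage_means(m, design))
  cl <- kmeans_cluster(sm, k = min(k, nrow(sm)), seed = seed,
                       n_restarts = n_restarts)
  asg <- assign_clusters_to_templates(cl, progression_templates(reverse = reverse),
                                      min_match = min_match, data = sm)
  if (!is.null(silhouette_cutoff))
    asg <- filter_by_silhouette(asg, silhouette_cutoff)
  asg
}
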