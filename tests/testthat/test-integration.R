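mk_pred <- function(mirna, gene, score, family = mirna) {
  data.frame(mirna = mirna, family = family, gene = gene,
             total_context_score = score, stringsAsFactors = FALSE)
}

test_that("context-score filter keeps the strongest tail per miRNA", {
  single <- mk_pred("miR-1", "GA", -0.1)
  expect_equal(nrow(filter_targets_by_context_score(single)), 1L)

  set.seed(61)
  scores <- sort(runif(100, -1, 0))
  many <- mk_pred(rep("miR-2", 100), paste0("G", 1:100), sample(scores))
  kept <- filter_targets_by_context_score(many, 0.05)
  expect_equal(nrow(kept), 5L)
  expect_setequal(kept$gene, many$gene[order(many$total_context_score)][1:5])

  ties <- mk_pred(rep("miR-3", 4), paste0("G", 1:4), rep(-0.5, 4))
  expect_equal(nrow(filter_targets_by_context_score(ties)), 4L)

  expect_error(filter_targets_by_context_score(single, quantile = 0), "\\(0, 1\\)")
})

test_that("context-score filter matches a brute-force quantile scan", {
  set.seed(67)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    pred <- mk_pred(sample(paste0("m", 1:4), n, replace = TRUE),
                    paste0("g", 1:n), runif(n, -1, 0))
    out <- filter_targets_by_context_score(pred, 0.1)
    for (mi in unique(pred$mirna)) {
      sc <- pred$total_context_score[pred$mirna == mi]
      cut <- if (length(sc) == 1) sc else quantile(sc, 0.1, type = 7)
      expect_setequal(out$gene[out$mirna == mi],
                      pred$gene[pred$mirna == mi & pred$total_context_score <= cut])
      expect_true(all(out$total_context_score[out$mirna == mi] <= cut + 1e-12))
    }
  }
})

test_that("family representatives have the lowest total context score", {
  pred <- mk_pred(c("b-mir", "a-mir", "c-mir"), paste0("g", 1:3),
                  c(-0.8, -0.5, -0.3), family = "fam1")
  expect_equal(unname(representative_mirna_per_family(pred)["fam1"]), "b-mir")

  lone <- mk_pred("m1", "g1", -0.2, family = "famX")
  expect_equal(unname(representative_mirna_per_family(lone)["famX"]), "m1")

  tie <- mk_pred(c("zzz", "aaa"), c("g1", "g2"), c(-0.4, -0.4), family = "famT")
  expect_equal(unname(representative_mirna_per_family(tie)["famT"]), "aaa")
})

test_that("integration keeps only predicted pairs sharing a timing group", {
  mi_asg <- structure(data.frame(
    feature = c("m1", "m2"), cluster = 1:2, template = c("G2", "G3"),
    match_score = 1, silhouette = NA_real_, reason = NA_character_,
    stringsAsFactors = FALSE), class = c("pattern_assignment", "data.frame"))
  ge_asg <- structure(data.frame(
    feature = c("g1", "g2", "g3"), cluster = 1:3,
    template = c("G2", "G7", NA), match_score = 1, silhouette = NA_real_,
    reason = NA_character_, stringsAsFactors = FALSE),
    class = c("pattern_assignment", "data.frame"))
  pred <- mk_pred(c("m1", "m1", "m2"), c("g1", "g2", "g3"), c(-0.9, -0.8, -0.7))
  tri <- integrate_mirna_mrna(mi_asg, ge_asg, pred)
  expect_equal(nrow(tri), 1L)            # only (m1, g1) shares group G2
  expect_identical(tri$gene, "g1")
  expect_identical(tri$group, "G2")
})

test_that("zero-noise synthetic integration recovers the planted pairs exactly", {
  study <- synth_study(small_config(seed = 71L))
  design <- study$design
  mi <- remove_zero_variance(study$mirna)$matrix
  mi_asg <- assign_patterns(mi, design, seed = 2)
  ge_sig <- suppressWarnings(anova_per_feature(study$gene, design))
  keep <- ge_sig$feature[ge_sig$q < 0.05]
  ge_asg <- assign_patterns(study$gene[keep, ], design, seed = 3, reverse = TRUE)
  filt <- filter_targets_by_context_score(study$targets)
  tri <- integrate_mirna_mrna(mi_asg, ge_asg, filt)
  got <- unique(paste(tri$mirna, tri$gene))
  want <- unique(paste(study$truth$planted_targets$mirna,
                       study$truth$planted_targets$gene))
  expect_setequal(got, want)
  # outputs are a subset of predictions and of assigned features
  expect_true(all(paste(tri$mirna, tri$gene) %in%
                    paste(filt$mirna, filt$gene)))
  expect_true(all(tri$mirna %in% mi_asg$feature[!is.na(mi_asg$template)]))
})

test_that("target pathways are selected by group-matched membership overlap", {
  tri <- data.frame(mirna = c("m1", "m2"), gene = c("g1", "g9"),
                    group = c("G2", "G3"), stringsAsFactors = FALSE)
  pw_asg <- structure(data.frame(
    feature = c("PW_HIT", "PW_WRONG_GROUP", "PW_NO_OVERLAP"),
    cluster = 1:3, template = c("G2", "G5", "G2"), match_score = 1,
    silhouette = 1, reason = NA_character_, stringsAsFactors = FALSE),
    class = c("pattern_assignment", "data.frame"))
  sets <- list(gene_set("PW_HIT", c("g1", "gx")),
               gene_set("PW_WRONG_GROUP", c("g1", "g9")),
               gene_set("PW_NO_OVERLAP", c("ga", "gb")))
  out <- derive_target_pathways(tri, pw_asg, sets)
  expect_identical(attr(out, "target_pathways"), "PW_HIT")
  expect_identical(out$pathway[out$gene == "g1"], "PW_HIT")
  expect_true(is.na(out$pathway[out$gene == "g9"]))
})

test_that("pathway ranking filters by thresholds and orders by |change| then p", {
  design <- default_stage_design()
  # three pathway score rows: strong early change, moderate, flat
  m <- rbind(strong = rep(c(0, 6, 6, 6), each = 3) + rep(c(-.1, 0, .1), 4),
             mid = rep(c(0, 3, 3, 3), each = 3) + rep(c(-.1, 0, .1), 4),
             flat = rnorm(12, 0, 0.05))
  colnames(m) <- design$sample_id
  m <- expression_matrix(m, "pathway")
  rk <- rank_top_pathways(m, design, "P->AT1", n_top = 2)
  expect_identical(rk$pathway, c("strong", "mid"))
  expect_identical(rk$rank, 1:2)
  empty <- rank_top_pathways(m, design, "DCIS->CA1D")
  expect_equal(nrow(empty), 0L)
  expect_error(rank_top_pathways(m, design, "P->DCIS"), "unknown transition")
})
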