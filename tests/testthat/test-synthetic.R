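test_that("zero-noise planted features follow their template stage means", {
  cfg <- generator_config(
    n_mirna = 1L, mirna_template_counts = c(G1 = 1L, G2 = 0L, G3 = 0L,
      G4 = 0L, G5 = 0L, G6 = 0L, G7 = 0L, G8 = 0L),
    n_mirna_zero_variance = 0L, n_gene = 2L,
    gene_template_counts = setNames(c(1L, rep(0L, 7)), paste0("G", 1:8)),
    noise_sd = 0, effect_size = 1, n_gene_sets = 1L, set_size = 1L,
    decoys_per_mirna = 0L, seed = 5L)
  ds <- generate_progression_dataset(cfg)
  sm <- stage_means(ds$mirna, ds$design)
  b <- sm[1, 1]
  expect_equal(unname(sm[1, ]), c(b, b + 1, b + 2, b + 3))
  # gene side is reversed: G1 gene decreases
  gm <- stage_means(ds$gene, ds$design)[1, ]
  expect_equal(unname(gm), c(gm[[1]], gm[[1]] - 1, gm[[1]] - 2, gm[[1]] - 3),
               ignore_attr = TRUE)
})

test_that("the generator is deterministic and respects planted structure", {
  cfg <- small_config(noise_sd = 0.5, seed = 42L)
  a <- generate_progression_dataset(cfg)
  b <- generate_progression_dataset(cfg)
  expect_identical(unclass(a$mirna), unclass(b$mirna))
  expect_identical(unclass(a$gene), unclass(b$gene))
  expect_identical(a$truth$mirna_pattern, b$truth$mirna_pattern)
  pa <- generate_target_map(a$truth, cfg)
  pb <- generate_target_map(b$truth, cfg)
  expect_identical(pa, pb)

  # template counts exceeding the total error out
  expect_error(generator_config(
    n_mirna = 5L, mirna_template_counts = setNames(rep(1L, 8), paste0("G", 1:8)),
    n_mirna_zero_variance = 0L), "exceed")
})

test_that("the design-size defaults reproduce the printed filter retentions", {
  cfg <- generator_config(seed = 2L)
  ds <- generate_progression_dataset(cfg)
  expect_equal(nrow(ds$mirna), 1983L)
  rep_mi <- remove_zero_variance(ds$mirna)$report
  expect_equal(rep_mi$n_removed, 1533L)
  expect_equal(rep_mi$n_retained, 450L)
  expect_equal(nrow(ds$gene), 17708L)
  rep_ge <- sd_quantile_filter(ds$gene, 0.25)$report
  expect_equal(rep_ge$n_retained, 13281L)
})

test_that("an all-constant matrix is fully removed by the variance filter", {
  cfg <- generator_config(
    n_mirna = 30L, mirna_template_counts = setNames(rep(0L, 8), paste0("G", 1:8)),
    n_mirna_zero_variance = 30L, n_gene = 10L,
    gene_template_counts = setNames(rep(0L, 8), paste0("G", 1:8)),
    n_gene_sets = 1L, set_size = 2L, seed = 8L)
  ds <- generate_progression_dataset(cfg)
  expect_equal(remove_zero_variance(ds$mirna)$report$n_retained, 0L)
})

test_that("planted target pairs survive the context-score filter; decoys mostly do not", {
  study <- synth_study(small_config(seed = 19L))
  filt <- filter_targets_by_context_score(study$targets, 0.05)
  planted <- paste(study$truth$planted_targets$mirna,
                   study$truth$planted_targets$gene)
  expect_true(all(planted %in% paste(filt$mirna, filt$gene)))
  expect_true(all(filt$total_context_score[
    paste(filt$mirna, filt$gene) %in% planted] <= -0.6))

  # no planted miRNAs -> decoys only is impossible, map is empty
  cfg0 <- generator_config(
    n_mirna = 10L, mirna_template_counts = setNames(rep(0L, 8), paste0("G", 1:8)),
    n_mirna_zero_variance = 0L, n_gene = 50L,
    gene_template_counts = setNames(c(5L, rep(0L, 7)), paste0("G", 1:8)),
    n_gene_sets = 2L, set_size = 3L, seed = 3L)
  ds0 <- generate_progression_dataset(cfg0)
  pred0 <- generate_target_map(ds0$truth, cfg0)
  expect_equal(nrow(pred0), 0L)
})

test_that("generated gene sets contain planted genes and honor requested counts", {
  cfg <- small_config(seed = 23L)
  study <- synth_study(cfg)
  expect_length(study$gene_sets, cfg$n_gene_sets)
  planted_sets <- study$truth$planted_enriched_sets
  expect_length(planted_sets, 8L * cfg$enriched_sets_per_group)
  names(study$gene_sets) <- vapply(study$gene_sets, `[[`, "", "name")
  targeted <- study$truth$planted_targets$gene
  for (nm in planted_sets) {
    grp <- sub("^PLANTED_(G[0-9]).*", "\\1", nm)
    members <- study$gene_sets[[nm]]$members
    pat <- study$truth$gene_pattern[members]
    expect_true(all(pat == grp))
    expect_gt(length(intersect(members, targeted)), 0L)
  }
  expect_error(generate_gene_sets(study$truth,
    small_config(set_size = 1000L)), "set_size")
})

test_that("raising the effect size never loses planted transition calls", {
  n_called <- vapply(c(2, 3, 4.5), function(es) {
    cfg <- small_config(seed = 29L)
    cfg$effect_size <- es
    cfg$noise_sd <- 0.5
    ds <- generate_progression_dataset(cfg)
    kept <- remove_zero_variance(ds$mirna)$matrix
    st <- suppressWarnings(anova_per_feature(kept, ds$design))
    pw <- suppressWarnings(tukey_hsd(kept, ds$design))
    calls <- attribute_transitions(pw, st, ds$design)
    planted <- names(ds$truth$mirna_pattern)[
      ds$truth$mirna_pattern %in% paste0("G", 1:8)]
    length(unique(intersect(calls$feature, planted)))
  }, 0)
  expect_true(all(diff(n_called) >= 0))
})

test_that("survival cohorts honor the censoring and effect parameters", {
  all_cens <- generate_survival_cohort(50, beta = 1, censor_rate = 1, seed = 4)
  expect_true(all(all_cens$event == 0))
  no_cens <- generate_survival_cohort(50, beta = 1, censor_rate = 0, seed = 4)
  expect_true(all(no_cens$event == 1))
  mid <- generate_survival_cohort(4000, beta = 0, censor_rate = 0.4, seed = 4)
  expect_lt(abs(mean(1 - mid$event) - 0.4), 0.05)
  expect_true(all(mid$time > 0))
  expect_true(all(as.character(mid$stage) %in% c("I", "II", "III", "IV")))
})

test_that("a written synthetic study round-trips through the readers", {
  outdir <- withr::local_tempdir()
  cfg <- small_config(noise_sd = 0.3, seed = 37L)
  paths <- write_synthetic_study(cfg, outdir, survival_n = 40L)
  mi <- read_expression_matrix(paths[["mirna"]], "miRNA")
  expect_equal(dim(mi), c(cfg$n_mirna, 12L))
  sets <- read_gmt(paths[["gmt"]])
  expect_length(sets, cfg$n_gene_sets)
  pred <- read_target_predictions(paths[["targets"]])
  expect_true(nrow(pred) > 0)
  surv <- read_survival_table(paths[["survival"]])
  expect_equal(nrow(surv), 40L)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(length(truth$mirna_pattern), cfg$n_mirna)
})
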