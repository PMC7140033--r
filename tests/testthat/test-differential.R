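test_that("one-way ANOVA matches hand-computed sums of squares", {
  hf <- hand_fixture()
  st <- anova_per_feature(hf$matrix, hf$design)
  expect_equal(st$F, 12)
  expect_equal(st$df_between, 3L)
  expect_equal(st$df_within, 8L)
  expect_equal(st$p, pf(12, 3, 8, lower.tail = FALSE))

  flat <- hf$matrix; flat[1, ] <- 5
  st0 <- anova_per_feature(flat, hf$design)
  expect_equal(st0$F, 0)
  expect_equal(st0$p, 1)

  # zero within-group variance with unequal means -> boundary p with warning
  deg <- hf$matrix; deg[1, ] <- rep(c(0, 1, 0, 0), each = 3)
  expect_warning(std <- anova_per_feature(deg, hf$design), "zero within-stage")
  expect_equal(std$p, 0)
})

test_that("ANOVA decomposition satisfies SSB + SSW = SST and matches aov", {
  design <- default_stage_design()
  set.seed(11)
  m <- matrix(rnorm(10 * 12), 10, 12,
              dimnames = list(paste0("f", 1:10), design$sample_id))
  st <- anova_per_feature(m, design)
  for (i in 1:10) {
    fit <- anova(aov(m[i, ] ~ design$stage))
    expect_equal(st$F[i], fit$`F value`[1], tolerance = 1e-9)
    expect_equal(st$p[i], fit$`Pr(>F)`[1], tolerance = 1e-9)
    sst <- sum((m[i, ] - mean(m[i, ]))^2)
    ssb_ssw <- sum(fit$`Sum Sq`)
    expect_equal(sst, ssb_ssw, tolerance = 1e-9)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.05)), c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("Tukey HSD reproduces the hand-computed studentized range statistic", {
  hf <- hand_fixture()
  pw <- tukey_hsd(hf$matrix, hf$design)
  ab <- pw[pw$stage_a == "P" & pw$stage_b == "AT1", ]
  expect_equal(ab$q_stat, 4 / sqrt(1 / 3), tolerance = 1e-9)  # ~6.928
  expect_equal(ab$mean_diff, 4)
  expect_equal(sign(ab$log2fc), sign(ab$mean_diff))
  expect_equal(nrow(pw), 6L)  # all stage pairs
  cd <- pw[pw$stage_a == "DCIS" & pw$stage_b == "CA1D", ]
  expect_equal(cd$q_stat, 0)

  # identical groups across the board
  m <- hf$matrix; m[1, ] <- rep(c(0, 1, 2), 4)
  pw2 <- tukey_hsd(m, hf$design)
  expect_true(all(pw2$q_stat == 0))
  expect_true(all(pw2$p_adj == 1))
})

test_that("studentized range tail matches t-reduction and quadrature oracle", {
  expect_equal(studentized_range_sf(0, 3, 10), 1)
  # k = 2: P(Q >= q) = P(|T_df| >= q / sqrt(2))
  for (q in c(0.5, 1.7, 3.2)) {
    for (df in c(4, 12)) {
      expect_lt(abs(studentized_range_sf(q, 2, df) -
                      2 * pt(q / sqrt(2), df, lower.tail = FALSE)), 1e-6)
    }
  }
  # monotone decreasing in q
  qs <- seq(0.1, 6, by = 0.35)
  expect_true(all(diff(studentized_range_sf(qs, 4, 8)) < 0))
  # quadrature oracle
  set.seed(5)
  for (case in 1:4) {
    q <- runif(1, 1, 5); k <- sample(3:5, 1); df <- sample(6:20, 1)
    expect_equal(studentized_range_sf(q, k, df), sr_sf_oracle(q, k, df),
                 tolerance = 1e-4)
  }
})

test_that("Tukey p-values for k = 2 designs match the t distribution", {
  design <- stage_design(paste0("s", 1:8), rep(c("A", "B"), each = 4), rep(1:4, 2))
  set.seed(8)
  m <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("f", 1:3), paste0("s", 1:8)))
  pw <- tukey_hsd(m, design)
  for (i in 1:3) {
    tt <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
    expect_equal(pw$p_adj[i], tt$p.value, tolerance = 1e-6)
  }
})

test_that("log fold changes are stage differences and antisymmetric", {
  hf <- hand_fixture()
  expect_equal(unname(log_fold_change(hf$matrix, hf$design, "P", "AT1")), 4)
  expect_equal(unname(log_fold_change(hf$matrix, hf$design, "DCIS", "CA1D")), 0)
  expect_error(log_fold_change(hf$matrix, hf$design, "P", "XXX"), "unknown stage")
  set.seed(13)
  m <- matrix(rnorm(5 * 12), 5, 12,
              dimnames = list(paste0("f", 1:5), hf$design$sample_id))
  expect_equal(log_fold_change(m, hf$design, "P", "DCIS"),
               -log_fold_change(m, hf$design, "DCIS", "P"))
})

test_that("transition attribution applies both thresholds on adjacent pairs only", {
  design <- default_stage_design()
  # planted G1-style: +3 per step, zero noise
  m <- rbind(up = rep(c(0, 3, 6, 9), each = 3),
             flat = rep(1, 12),
             late = rep(c(0, 0, 0, 4), each = 3))
  colnames(m) <- design$sample_id
  st <- suppressWarnings(anova_per_feature(m, design))
  pw <- suppressWarnings(tukey_hsd(m, design))
  calls <- attribute_transitions(pw, st, design)
  expect_setequal(calls$transition[calls$feature == "up"],
                  c("P->AT1", "AT1->DCIS", "DCIS->CA1D"))
  expect_true(all(calls$direction[calls$feature == "up"] == "up"))
  expect_false("flat" %in% calls$feature)
  expect_identical(calls$transition[calls$feature == "late"], "DCIS->CA1D")
  # non-adjacent pairs are never attributed even when extreme
  expect_false(any(!calls$transition %in%
                     c("P->AT1", "AT1->DCIS", "DCIS->CA1D")))
})

test_that("Venn partition counts match brute-force set arithmetic", {
  tr <- c("P->AT1", "AT1->DCIS", "DCIS->CA1D")
  one <- data.frame(feature = "f1", transition = tr,
                    direction = "up", stringsAsFactors = FALSE)
  v1 <- venn_partition(one, tr)
  expect_equal(unname(v1[paste(tr, collapse = " & ")]), 1L)
  expect_equal(sum(v1), 1L)

  disj <- data.frame(feature = c("a", "b", "c"), transition = tr,
                     direction = "up", stringsAsFactors = FALSE)
  vd <- venn_partition(disj, tr)
  expect_equal(unname(vd[tr]), rep(1L, 3))
  expect_equal(sum(vd), 3L)

  set.seed(21)
  for (rep in 1:10) {
    feats <- paste0("f", 1:30)
    calls <- do.call(rbind, lapply(feats, function(f) {
      sel <- tr[runif(3) < 0.5]
      if (!length(sel)) return(NULL)
      data.frame(feature = f, transition = sel, direction = "up",
                 stringsAsFactors = FALSE)
    }))
    v <- venn_partition(calls, tr)
    expect_equal(sum(v), length(unique(calls$feature)))
    # brute force each region
    sets <- lapply(tr, function(t) unique(calls$feature[calls$transition == t]))
    names(sets) <- tr
    in123 <- Reduce(intersect, sets)
    expect_equal(unname(v[paste(tr, collapse = " & ")]), length(in123))
    only1 <- setdiff(sets[[1]], union(sets[[2]], sets[[3]]))
    expect_equal(unname(v[tr[1]]), length(only1))
  }
})
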