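#' Configuration for the synthetic progression-study generator
#'
#' Defaults emulate the study design the pipeline was built around: a
#' four-stage triplicate panel with 1,983 annotated miRNAs of which 1,533
#' are constant (zero variance), 17,708 genes, gene pattern-group sizes
#' (946, 1751, 452, 166, 248, 299, 1126, 413), 213 pattern-following miRNAs
#' with 177 rising and none in G8, steps of 3 log2 units per active
#' transition, and replicate noise at a quarter of the step size.
#'
#' @param n_mirna,n_gene Total feature counts.
#' @param mirna_template_counts,gene_template_counts Planted features per
#'   template G1..G8 (named or positional length-8 integer vectors). Gene
#'   groups follow the reversed (gene-side) orientation.
#' @param n_mirna_zero_variance Constant miRNA rows (the uninformative
#'   fraction removed by the variance filter).
#' @param frac_gene_zero_variance Fraction of genes made constant.
#' @param effect_size Log2 step per active transition.
#' @param noise_sd SD of additive Gaussian replicate noise (log2 units).
#' @param baseline_range Range of per-feature baselines (log2 units).
#' @param n_gene_sets Total gene sets; `set_size` members each.
#' @param set_size Members per generated set.
#' @param decoys_per_mirna Weak decoy target predictions per planted miRNA.
#' @param targets_per_mirna Planted strong targets per miRNA (kept small so
#'   the per-miRNA 5% context-score quantile retains every planted pair).
#' @param enriched_sets_per_group Enriched gene sets per planted pattern
#'   group (>= 2 keeps their within-cluster silhouettes high).
#' @param stages Ordered stage labels.
#' @param n_rep Replicates per stage.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(
    n_mirna = 1983L,
    mirna_template_counts = c(G1 = 60L, G2 = 70L, G3 = 30L, G4 = 17L,
                              G5 = 10L, G6 = 12L, G7 = 14L, G8 = 0L),
    n_mirna_zero_variance = 1533L,
    n_gene = 17708L,
    gene_template_counts = c(G1 = 946L, G2 = 1751L, G3 = 452L, G4 = 166L,
                             G5 = 248L, G6 = 299L, G7 = 1126L, G8 = 413L),
    frac_gene_zero_variance = 0,
    effect_size = 3,
    noise_sd = effect_size / 4,
    baseline_range = c(4, 12),
    n_gene_sets = 100L,
    set_size = 30L,
    decoys_per_mirna = 30L,
    targets_per_mirna = 1L,
    enriched_sets_per_group = 3L,
    stages = c("P", "AT1", "DCIS", "CA1D"),
    n_rep = 3L,
    seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna),
              mirna_template_counts = setNames(as.integer(mirna_template_counts),
                                               paste0("G", 1:8)),
              n_mirna_zero_variance = as.integer(n_mirna_zero_variance),
              n_gene = as.integer(n_gene),
              gene_template_counts = setNames(as.integer(gene_template_counts),
                                              paste0("G", 1:8)),
              frac_gene_zero_variance = frac_gene_zero_variance,
              effect_size = effect_size, noise_sd = noise_sd,
              baseline_range = baseline_range,
              n_gene_sets = as.integer(n_gene_sets),
              set_size = as.integer(set_size),
              decoys_per_mirna = decoys_per_mirna,
              targets_per_mirna = as.integer(targets_per_mirna),
              enriched_sets_per_group = as.integer(enriched_sets_per_group),
              stages = stages, n_rep = as.integer(n_rep),
              seed = as.integer(seed))
  n_gz <- round(cfg$frac_gene_zero_variance * cfg$n_gene)
  if (sum(cfg$mirna_template_counts) + cfg$n_mirna_zero_variance > cfg$n_mirna)
    stop("miRNA template + zero-variance counts exceed n_mirna")
  if (sum(cfg$gene_template_counts) + n_gz > cfg$n_gene)
    stop("gene template + zero-variance counts exceed n_gene")
  if (cfg$frac_gene_zero_variance < 0 || cfg$frac_gene_zero_variance > 1)
    stop("frac_gene_zero_variance must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$set_size > cfg$n_gene) stop("set_size exceeds n_gene")
  structure(cfg, class = "generator_config")
}

# One synthetic matrix: planted templates + zero-variance + flat-noise rows.
# `reverse` switches to the gene-side template orientation.
.synth_matrix <- function(n, template_counts, n_zero_var, prefix, cfg, reverse) {
  shapes <- progression_templates(reverse = reverse)
  n_stage <- length(cfg$stages)
  n_col <- n_stage * cfg$n_rep
  pattern <- c(rep(names(template_counts), times = template_counts),
               rep("none", n_zero_var),
               rep("flat", n - sum(template_counts) - n_zero_var))
  ids <- sprintf("%s%05d", prefix, seq_len(n))
  baseline <- runif(n, cfg$baseline_range[1L], cfg$baseline_range[2L])
  means <- matrix(baseline, nrow = n, ncol = n_stage)
  planted <- pattern %in% rownames(shapes)
  if (any(planted))
    means[planted, ] <- means[planted, ] +
      cfg$effect_size * shapes[pattern[planted], , drop = FALSE]
  vals <- means[, rep(seq_len(n_stage), each = cfg$n_rep), drop = FALSE]
  noisy <- pattern != "none"
  if (cfg$noise_sd > 0 && any(noisy))
    vals[noisy, ] <- vals[noisy, ] +
      matrix(rnorm(sum(noisy) * n_col, 0, cfg$noise_sd), ncol = n_col)
  design <- default_stage_design(cfg$stages, cfg$n_rep)
  dimnames(vals) <- list(ids, design$sample_id)
  list(values = vals, pattern = setNames(pattern, ids),
       effect = setNames(ifelse(planted, cfg$effect_size, 0), ids))
}

#' Generate a synthetic progression dataset with planted truth
#'
#' Produces the miRNA and gene expression matrices (log2 scale), the stage
#' design, and a truth record. Planted features follow their template's
#' stage means (baseline plus `effect_size` per active transition;
#' gene-side groups reversed) with additive Normal(0, `noise_sd`) replicate
#' noise; zero-variance features are constant across all samples; remaining
#' features are flat with noise.
#'
#' @param config A [generator_config()].
#' @return List: `mirna` ([expression_matrix()]), `gene`, `design`
#'   ([stage_design()]), `truth` (list of class `synthetic_truth` with
#'   `mirna_pattern`, `gene_pattern`, `planted_effect`, and slots filled in
#'   by [generate_target_map()], [generate_gene_sets()],
#'   [generate_survival_cohort()]).
#' @export
generate_progression_dataset <- function(config = generator_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    mi <- .synth_matrix(cfg$n_mirna, cfg$mirna_template_counts,
                        cfg$n_mirna_zero_variance, "miR-", cfg,
                        reverse = FALSE)
    n_gz <- round(cfg$frac_gene_zero_variance * cfg$n_gene)
    ge <- .synth_matrix(cfg$n_gene, cfg$gene_template_counts, n_gz, "GENE",
                        cfg, reverse = TRUE)
  })
  truth <- structure(list(
    mirna_pattern = mi$pattern, gene_pattern = ge$pattern,
    planted_effect = c(mi$effect, ge$effect),
    planted_targets = NULL, planted_enriched_sets = NULL,
    survival_beta = NULL), class = "synthetic_truth")
  list(mirna = expression_matrix(mi$values, "miRNA"),
       gene = expression_matrix(ge$values, "gene"),
       design = default_stage_design(cfg$stages, cfg$n_rep),
       truth = truth)
}

#' Generate a planted miRNA-target prediction map
#'
#' Each planted miRNA of group Gk is linked to `targets_per_mirna` planted
#' genes of group Gk (the gene orientation is already reversed in the
#' dataset), with strong context scores drawn Uniform(-1.0, -0.6); genes are
#' handed out round-robin so targets stay distinct while the group's gene
#' pool lasts. Each planted miRNA additionally receives `decoys_per_mirna`
#' weak decoy predictions against background genes, scored Uniform(-0.2, 0),
#' so the per-miRNA 5% quantile cutoff always retains the planted pairs.
#' Each miRNA is its own family.
#'
#' @param truth Truth record from [generate_progression_dataset()] (updated
#'   in the returned attribute).
#' @param config The same [generator_config()].
#' @return Target-prediction data frame; the planted (non-decoy) pairs are
#'   recorded in attribute `truth` (an updated `synthetic_truth`).
#' @export
generate_target_map <- function(truth, config) {
  cfg <- config
  flat_genes <- names(truth$gene_pattern)[truth$gene_pattern == "flat"]
  rows <- list()
  with_seed(cfg$seed + 1L, {
    for (g in paste0("G", 1:8)) {
      mirnas <- names(truth$mirna_pattern)[truth$mirna_pattern == g]
      genes <- names(truth$gene_pattern)[truth$gene_pattern == g]
      if (!length(mirnas) || !length(genes)) next
      mir <- rep(mirnas, each = cfg$targets_per_mirna)
      gen <- rep_len(genes, length(mir))
      dup <- duplicated(paste(mir, gen))
      rows[[g]] <- data.frame(
        mirna = mir[!dup], family = mir[!dup], gene = gen[!dup],
        total_context_score = runif(sum(!dup), -1.0, -0.6),
        planted = TRUE, stringsAsFactors = FALSE)
    }
    planted <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mirna = character(0), family = character(0),
                 gene = character(0), total_context_score = numeric(0),
                 planted = logical(0), stringsAsFactors = FALSE)
    decoys <- NULL
    all_planted_mirnas <- names(truth$mirna_pattern)[
      truth$mirna_pattern %in% paste0("G", 1:8)]
    if (cfg$decoys_per_mirna > 0 && length(all_planted_mirnas) &&
        length(flat_genes)) {
      decoys <- do.call(rbind, lapply(all_planted_mirnas, function(mi) {
        gs <- sample(flat_genes, min(cfg$decoys_per_mirna, length(flat_genes)))
        data.frame(mirna = mi, family = mi, gene = gs,
                   total_context_score = runif(length(gs), -0.2, 0),
                   planted = FALSE, stringsAsFactors = FALSE)
      }))
    }
  })
  pred <- rbind(planted, decoys)
  rownames(pred) <- NULL
  truth$planted_targets <- pred[pred$planted, c("mirna", "gene")]
  pred$planted <- NULL
  attr(pred, "truth") <- truth
  pred
}

#' Generate gene sets with planted enrichment
#'
#' `enriched_sets_per_group` enriched sets per pattern group that has both
#' planted miRNAs and planted genes, drawn from that group's planted genes
#' and always including targeted genes of the group (so every enriched set
#' overlaps the integrated miRNA-mRNA list); the remaining sets are null
#' sets drawn uniformly from the background (non-planted) genes.
#'
#' @param truth Truth record, after [generate_target_map()] so the planted
#'   target pairs are known.
#' @param config The same [generator_config()].
#' @return List of [gene_set()] objects; attribute `truth` carries the
#'   updated truth with `planted_enriched_sets`.
#' @export
generate_gene_sets <- function(truth, config) {
  cfg <- config
  flat_genes <- names(truth$gene_pattern)[truth$gene_pattern == "flat"]
  sets <- list()
  enriched_names <- character(0)
  targeted <- if (!is.null(truth$planted_targets)) truth$planted_targets$gene
              else character(0)
  with_seed(cfg$seed + 2L, {
    for (g in paste0("G", 1:8)) {
      genes <- names(truth$gene_pattern)[truth$gene_pattern == g]
      mirnas <- names(truth$mirna_pattern)[truth$mirna_pattern == g]
      if (!length(genes) || !length(mirnas)) next
      hit <- intersect(genes, targeted)
      for (i in seq_len(cfg$enriched_sets_per_group)) {
        nm <- sprintf("PLANTED_%s_%02d", g, i)
        core <- if (length(hit)) sample(hit, min(3L, length(hit))) else character(0)
        pool <- setdiff(genes, core)
        extra <- if (length(pool) > cfg$set_size - length(core))
          sample(pool, cfg$set_size - length(core)) else pool
        sets[[nm]] <- gene_set(nm, c(core, extra), collection = "SYNTH")
        enriched_names <- c(enriched_names, nm)
      }
    }
    n_null <- cfg$n_gene_sets - length(sets)
    if (n_null > 0 && length(flat_genes) >= 2L) {
      for (i in seq_len(n_null)) {
        nm <- sprintf("NULL_SET_%04d", i)
        sets[[nm]] <- gene_set(
          nm, sample(flat_genes, min(cfg$set_size, length(flat_genes))),
          collection = "SYNTH")
      }
    }
  })
  truth$planted_enriched_sets <- enriched_names
  out <- unname(sets)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic survival cohort with a median-split marker effect
#'
#' Marker values are Normal; subjects with below-median marker have their
#' exponential event hazard multiplied by exp(`beta`), i.e. `beta` is the
#' true log hazard ratio of the Low group against High. Censoring is
#' independent Uniform(0, u) with u calibrated so the expected censoring
#' fraction is `censor_rate`. Age (Normal, mean 58, SD 12, clipped to
#' 25..90) and stage (I:II:III:IV = 0.20:0.45:0.25:0.10) are drawn
#' independently of the marker.
#'
#' @param n Cohort size (>= 2).
#' @param beta True log hazard ratio of the Low-marker group.
#' @param censor_rate Target censoring fraction in \[0, 1\].
#' @param seed RNG seed.
#' @param baseline_median Median event time (months) in the High group.
#' @return Survival-record data frame (see [survival_records()]) with the
#'   generating parameters in attribute `truth`.
#' @export
generate_survival_cohort <- function(n, beta = log(2), censor_rate = 0.3,
                                     seed = 1L, baseline_median = 60) {
  if (n < 2L) stop("need n >= 2")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  lambda0 <- log(2) / baseline_median
  with_seed(seed, {
    marker <- rnorm(n, mean = 10, sd = 1)
    low <- marker <= median(marker)
    lambda <- lambda0 * exp(beta * low)
    t_event <- rexp(n, rate = lambda)
    if (censor_rate >= 1) {
      time <- runif(n, 0.01, baseline_median)
      event <- rep(0L, n)
    } else if (censor_rate <= 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      lbar <- mean(lambda)
      # (1 - exp(-x)) / x = censor_rate, x = lbar * u
      x <- uniroot(function(x) (1 - exp(-x)) / x - censor_rate,
                   lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      cens <- runif(n, 0, x / lbar)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    age <- pmin(pmax(round(rnorm(n, 58, 12)), 25), 90)
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = c(0.20, 0.45, 0.25, 0.10))
  })
  rec <- survival_records(subject_id = sprintf("S%05d", seq_len(n)),
                          time = pmax(time, 1e-6), event = event, age = age,
                          stage = stage, marker = marker)
  attr(rec, "truth") <- list(survival_beta = beta, censor_rate = censor_rate,
                             baseline_median = baseline_median)
  rec
}

#' Write a complete synthetic study to a directory
#'
#' Generates the full input bundle (matrices, design, target predictions,
#' GMT, survival table, truth JSON) under `outdir`.
#'
#' @param config A [generator_config()].
#' @param outdir Output directory (created if needed).
#' @param survival_n,survival_beta,survival_censor_rate Cohort parameters.
#' @return Invisible named character vector of paths written.
#' @export
write_synthetic_study <- function(config = generator_config(), outdir,
                                  survival_n = 500L,
                                  survival_beta = log(2),
                                  survival_censor_rate = 0.3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_progression_dataset(config)
  pred <- generate_target_map(ds$truth, config)
  truth <- attr(pred, "truth")
  sets <- generate_gene_sets(truth, config)
  truth <- attr(sets, "truth")
  cohort <- generate_survival_cohort(survival_n, survival_beta,
                                     survival_censor_rate,
                                     seed = config$seed + 3L)
  truth$survival_beta <- survival_beta
  paths <- c(mirna = file.path(outdir, "mirna_matrix.tsv"),
             gene = file.path(outdir, "gene_matrix.tsv"),
             design = file.path(outdir, "design.tsv"),
             targets = file.path(outdir, "target_predictions.tsv"),
             gmt = file.path(outdir, "gene_sets.gmt"),
             survival = file.path(outdir, "survival.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_expression_matrix(ds$mirna, paths[["mirna"]])
  write_expression_matrix(ds$gene, paths[["gene"]])
  write.table(ds$design, paths[["design"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(pred, paths[["targets"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gmt(sets, paths[["gmt"]])
  write.table(cohort, paths[["survival"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(mirna_pattern = as.list(truth$mirna_pattern),
         gene_pattern = as.list(truth$gene_pattern),
         planted_targets = truth$planted_targets,
         planted_enriched_sets = truth$planted_enriched_sets,
         survival_beta = truth$survival_beta),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
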