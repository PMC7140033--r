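# mirProgression

Multilevel miRNA–mRNA–pathway integromics across ordered tumor-progression
stages.

## What this package is for

Stepwise cancer progression models — the canonical example being the
isogenic MCF10A breast panel (normal-like **P** → preneoplastic **AT1** →
ductal carcinoma in situ **DCIS** → invasive **CA1D**, profiled in
triplicate) — pose a recurring analysis problem: which miRNAs, genes and
pathways change at which histologic transition, in which direction, and how
do the three molecular layers connect? `mirProgression` implements that
analysis as a tested, reusable pipeline for anyone working with
feature-by-sample expression matrices over an ordered stage design:

1. **Filtering** — removal of zero-variance features; SD-quantile filtering
   (rows with SD at or above the *q* = 0.25 quantile of all row SDs are
   kept); quantile normalization.
2. **Differential inference** — per-feature one-way ANOVA across stages with
   Benjamini–Hochberg FDR control; Tukey HSD post-hoc contrasts on all stage
   pairs; attribution of changes to adjacent transitions
   (|log2FC| ≥ 2 and Tukey adjusted *p* < 0.01 by default); Venn partition
   of transition calls.
3. **Pattern mapping** — K-means clustering of standardized per-stage mean
   profiles and matching of cluster centroids to eight predefined
   progression templates: G1 early continuous increase (0,1,2,3), G2 early
   increase then plateau (0,1,1,1), G3 delayed increase (0,0,1,1), G4 late
   increase (0,0,0,1), and their sign mirrors G5–G8. Gene and pathway
   profiles use the reversed orientation (a group-Gk gene moves opposite to
   a group-Gk miRNA). Silhouette widths gate assignment quality
   (cutoff 0.5 for pathways).
4. **Pathway scoring** — parametric analysis of gene set enrichment (PAGE):
   for a set with *m* matched members and member mean *S&#8202;m* in a sample whose
   genes have mean μ and SD δ,

   Z = (S&#8202;m − μ) · √m / δ

5. **Integration** — TargetScan-style predictions filtered per miRNA at the
   5% total-context-score quantile; (miRNA, gene) pairs kept when both map
   to the same timing group with opposite directions; target pathways
   derived by gene-membership overlap with the integrated list; most-altered
   pathways ranked per transition.
6. **Networks** — miRNA→gene (`targets`) and gene→pathway (`member_of`)
   edges weighted by Pearson correlation of 12-sample profiles, with
   Ward-linkage ordering on 1 − r for heat maps; TSV + GraphML export.
7. **Survival** — median split of a marker, Kaplan–Meier curves, two-group
   log-rank test, multivariate Cox regression (Efron ties) on marker group,
   age and stage.

A **synthetic-data generator** with known planted truth emulates the whole
study design (templates, zero-variance fraction, replicate noise,
suppressor-miRNA/target-gene maps, enriched gene sets, proportional-hazards
survival cohorts), so every stage of the pipeline is testable end to end
without any external data.

## Worked example

```r
library(mirProgression)

cfg <- generator_config(
  n_mirna = 120, mirna_template_counts = setNames(rep(8L, 8), paste0("G", 1:8)),
  n_mirna_zero_variance = 20, n_gene = 400,
  gene_template_counts = setNames(rep(20L, 8), paste0("G", 1:8)),
  noise_sd = 0.75, n_gene_sets = 60, set_size = 10, seed = 1)
ds      <- generate_progression_dataset(cfg)
targets <- generate_target_map(ds$truth, cfg)
sets    <- generate_gene_sets(attr(targets, "truth"), cfg)

res <- run_pipeline(ds$mirna, ds$gene, ds$design, sets, targets,
                    config = pipeline_config(seed = 11, normalize_genes = FALSE))
res
#> Progression integromics pipeline
#>   miRNA: 120 -> 100 after zero-variance filter; 66 significant; 66 pattern-assigned
#>   genes: 400 -> 300 after SD filter; 166 significant; 166 pattern-assigned
#>   pathways: 60 scored; 22 assigned; 13 target pathways
#>   integration: 58 pairs over 58 genes; network 128 nodes / 110 edges
```

The 20 constant miRNAs are dropped by the variance filter; of the noisy
remainder, the planted pattern-following features dominate the significant
list and are mapped back to their templates:

```r
head(res$mirna_assignment, 3)
#>     feature cluster template match_score silhouette reason
#> 1 miR-00001       6       G3   0.9991577 0.02772034   <NA>
#> 2 miR-00002       7       G1   0.9990225 0.75594981   <NA>
#> 3 miR-00003       7       G1   0.9990225 0.70746316   <NA>

res$top_pathways[res$top_pathways$transition == "P->AT1", ]
#>         pathway transition delta_score        p_adj rank
#> 1 PLANTED_G7_02     P->AT1    4.179670 2.918194e-08    1
#> 2 PLANTED_G7_01     P->AT1    3.815613 2.345183e-08    2
```

The two top-ranked pathways at the first transition are planted enriched
sets whose PAGE scores jump by ~4 Z-units between P and AT1 with tiny Tukey
adjusted p-values. Survival analysis on a synthetic cohort with a true
hazard ratio of 2 for the low-marker group:

```r
rec <- generate_survival_cohort(500, beta = log(2), censor_rate = 0.3, seed = 2)
logrank_test(rec, median_split(rec))[c("chisq", "p")]
#> $chisq
#> [1] 50.66904
#> $p
#> [1] 1.093304e-12

cox_ph_fit(rec)[1, ]
#>              term      coef       HR   CI_low  CI_high            p
#> 1 marker_groupLow 0.8049227 2.236524 1.786069 2.800585 2.306266e-12
```

The Cox hazard ratio for the Low group (2.24, 95% CI 1.79–2.80) brackets the
planted value of 2.

## Layout

- `R/` — implementation (I/O, preprocessing, differential, patterns, PAGE,
  integration, network, survival, synthetic data, pipeline orchestration)
- `tests/testthat/` — unit, property and end-to-end acceptance tests with
  independent oracles (quadrature studentized-range tail, brute-force
  silhouette and BH, permutation log-rank, grid-search Cox likelihood)
- `vignettes/progression-integromics.Rmd` — methods vignette: the models,
  default parameters, generator assumptions and numerical conventions
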