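# Independent oracles used across the suite. These deliberately re-derive
# quantities from definitions rather than calling the implementation paths
# they check.

# Studentized-range upper tail by nested numerical integration of the
# density of the range of k N(0,1) means studentized by sqrt(chisq_df/df).
sr_sf_oracle <- function(q, k, df) {
  inner <- function(s) vapply(s, function(si)
    integrate(function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q * si))^(k - 1),
              -Inf, Inf, rel.tol = 1e-10)$value, 0)
  fs <- function(s)
    2 * exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(s) -
              df * s^2 / 2)
  1 - integrate(function(s) fs(s) * inner(s), 0, Inf, rel.tol = 1e-9)$value
}

# Benjamini-Hochberg step-up from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(q_sorted, 1)[order(o)]
}

# Silhouette widths from pairwise Euclidean distances, straight from the
# definition.
silhouette_oracle <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    same <- which(labels == own & seq_len(n) != i)
    if (!length(same)) return(0)
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), own),
                    function(cl) mean(d[i, labels == cl]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
}

# Kaplan-Meier product-limit from the definition, evaluated at time t.
km_oracle_at <- function(time, event, t) {
  ev_times <- sort(unique(time[event == 1 & time <= t]))
  s <- 1
  for (ti in ev_times) {
    d <- sum(time == ti & event == 1)
    n_at <- sum(time >= ti)
    s <- s * (1 - d / n_at)
  }
  s
}

# A small balanced 4-stage x 3-replicate matrix with the hand-computable
# groups (0,1,2), (4,5,6), (0,1,2), (0,1,2) in its first row.
hand_fixture <- function() {
  design <- default_stage_design()
  m <- matrix(c(0, 1, 2, 4, 5, 6, 0, 1, 2, 0, 1, 2), nrow = 1,
              dimnames = list("f1", design$sample_id))
  list(matrix = m, design = design)
}

# Small planted configuration shared by recovery tests.
small_config <- function(noise_sd = 0, seed = 101L, ...) {
  generator_config(
    n_mirna = 120L,
    mirna_template_counts = setNames(rep(8L, 8), paste0("G", 1:8)),
    n_mirna_zero_variance = 20L,
    n_gene = 400L,
    gene_template_counts = setNames(rep(20L, 8), paste0("G", 1:8)),
    noise_sd = noise_sd, n_gene_sets = 60L, set_size = 10L,
    decoys_per_mirna = 20L, seed = seed, ...)
}

# Generate a full synthetic study in memory.
synth_study <- function(config) {
  ds <- generate_progression_dataset(config)
  pred <- generate_target_map(ds$truth, config)
  truth <- attr(pred, "truth")
  sets <- generate_gene_sets(truth, config)
  ds$truth <- attr(sets, "truth")
  ds$targets <- pred
  ds$gene_sets <- sets
  ds
}
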