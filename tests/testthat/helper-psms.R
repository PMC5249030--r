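# shared fixtures and independent oracles for the test suite

# tiny hand-written PSM table (2 decoys, 3 targets)
toy_psms <- function() {
  tibble::tibble(
    spectrum_id = paste0("s", 1:5),
    peptide = c("AAS*K", "AAK", "ELVISK", "PEPTIDER", "MK"),
    charge = c(2L, 2L, 3L, 2L, 3L),
    protein_accession = c("P00001", "REV_P00002", "P00003", "REV_P00004", "P00005"),
    class_label = c(1L, 0L, 1L, 0L, 1L),
    delta_cn = c(0.35, 0.02, 0.22, 0.01, 0.4),
    xcorr = c(3.4, 1.2, 2.8, 0.9, 4.1),
    delta_m = c(0.002, -0.8, 0.01, 0.5, -0.003),
    sp_rank = c(1, 12, 2, 30, 1),
    perc_ions = c(0.7, 0.2, 0.55, 0.15, 0.8),
    rt_pvalue = c(0.05, 0.6, 0.1, 0.9, 0.02)
  )
}

# independent filter-and-count FDR oracle (same degenerate conventions)
brute_fdr <- function(labels, probs, t) {
  acc <- probs >= t
  fp <- sum(labels[acc] == 0)
  tp <- sum(labels[acc] == 1)
  if (tp == 0) {
    if (fp == 0) return(0)
    return(1)
  }
  fp / tp
}

# brute-force best sensitivity at an FDR bound: max accepted targets over
# every candidate threshold (including "accept nothing" = 0)
brute_best_sensitivity <- function(labels, probs, fdr_bound) {
  best <- 0L
  for (t in unique(probs)) {
    if (brute_fdr(labels, probs, t) <= fdr_bound) {
      best <- max(best, sum(probs >= t & labels == 1))
    }
  }
  best
}

# rank-statistic AUC oracle: Mann-Whitney U / (n1 * n0), ties = 1/2
rank_auc <- function(labels, probs) {
  r <- rank(probs)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# well-separated two-cloud dataset: class 1 high on every informative score
separable_psms <- function(n_per_class = 150, seed = 42) {
  withr::with_seed(seed, {
    lab <- rep(c(0L, 1L), each = n_per_class)
    n <- 2 * n_per_class
    tibble::tibble(
      spectrum_id = sprintf("sep_%04d", seq_len(n)),
      peptide = rep("PEPTIDEK", n),
      charge = rep(2L, n),
      protein_accession = ifelse(lab == 0L, "REV_P1", "P1"),
      class_label = lab,
      delta_cn = ifelse(lab == 1L, runif(n, 0.3, 0.5), runif(n, 0, 0.05)),
      xcorr = ifelse(lab == 1L, runif(n, 3.5, 5), runif(n, 0.5, 1.5)),
      delta_m = ifelse(lab == 1L, rnorm(n, 0, 0.005), runif(n, -1, 1)),
      sp_rank = ifelse(lab == 1L, 1, sample(10:50, n, replace = TRUE)),
      perc_ions = ifelse(lab == 1L, runif(n, 0.7, 0.95), runif(n, 0.05, 0.3)),
      rt_pvalue = ifelse(lab == 1L, runif(n, 0, 0.1), runif(n, 0.4, 1))
    )
  })
}

# shared cache for expensive acceptance-scale simulation results
.acceptance_cache <- new.env(parent = emptyenv())

# one full-sweep pipeline run per seed on the default-scale synthetic preset
# (default hyperparameters); memoised so several tests can share the runs
calibration_runs <- function(seeds = 1:10) {
  key <- paste0("runs_", paste(seeds, collapse = "_"))
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  runs <- lapply(seeds, function(s) {
    sim <- simulate_psms(n_targets = 5000, n_decoys = 5000,
                         frac_correct = 0.15, seed = s)
    res <- rescore_psms(sim$psms, ann_hyperparams(seed = s))
    list(seed = s, sim = sim, res = res)
  })
  .acceptance_cache[[key]] <- runs
  runs
}
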