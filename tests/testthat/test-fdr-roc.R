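test_that("the decoy-counting estimate matches direct arithmetic", {
  # 1 decoy and 100 targets at or above threshold -> 1/100
  labels <- c(0, rep(1, 100))
  probs <- c(0.9, seq(0.5, 1, length.out = 100))
  expect_equal(estimate_fdr(labels, probs, 0.5), 1 / 100)
  # no decoys above the threshold
  expect_equal(estimate_fdr(c(0, 1, 1), c(0.1, 0.8, 0.9), 0.5), 0)
  # no targets above but decoys above: capped infinite-rate sentinel
  expect_equal(estimate_fdr(c(0, 1), c(0.9, 0.1), 0.5), 1)
  # nothing above
  expect_equal(estimate_fdr(c(0, 1), c(0.1, 0.1), 0.5), 0)
  expect_error(estimate_fdr(numeric(0), numeric(0), 0.5), "empty")
})

test_that("estimate_fdr equals the brute-force filter-and-count oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(3:40, 1)
      labels <- sample(0:1, n, replace = TRUE)
      probs <- round(runif(n), 2) # coarse grid to force ties
      t <- sample(c(probs, runif(1)), 1)
      expect_equal(estimate_fdr(labels, probs, t), brute_fdr(labels, probs, t))
    }
  })
})

test_that("threshold statistics enumerate the hand-worked sweep", {
  psms <- tibble::tibble(
    spectrum_id = c("a", "b", "c"),
    class_label = c(1L, 0L, 1L),
    raw_prob = c(0.9, 0.8, 0.7)
  )
  stats <- compute_threshold_stats(psms)
  expect_equal(nrow(stats), 4) # sentinel + 3 distinct values
  expect_true(all(diff(stats$threshold) < 0))
  at <- function(t) stats[which(stats$threshold == t), ]
  expect_equal(at(0.9)$tp, 1); expect_equal(at(0.9)$fp, 0)
  expect_equal(at(0.9)$est_fdr, 0)
  expect_equal(at(0.8)$tp, 1); expect_equal(at(0.8)$fp, 1)
  expect_equal(at(0.8)$est_fdr, 1)
  expect_equal(at(0.7)$tp, 2); expect_equal(at(0.7)$fp, 1)
  expect_equal(at(0.7)$est_fdr, 0.5)
  # sentinel accepts nothing
  expect_equal(stats$tp[1], 0)
  expect_equal(stats$fp[1], 0)
  # count bookkeeping at every point
  expect_true(all(stats$tp + stats$fn == 2))
  expect_true(all(stats$fp + stats$tn == 1))

  # tie collapse: identical probabilities give a single operating point
  tied <- tibble::tibble(spectrum_id = letters[1:4],
                         class_label = c(1L, 0L, 1L, 0L),
                         raw_prob = rep(0.5, 4))
  st <- compute_threshold_stats(tied)
  expect_equal(nrow(st), 2)
  expect_equal(st$tp[2], 2)
  expect_equal(st$fp[2], 2)

  expect_error(compute_threshold_stats(dplyr::select(psms, -"raw_prob")),
               "raw_prob")
})

test_that("threshold statistics agree with brute-force counting on random data", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(10:80, 1)
      psms <- tibble::tibble(
        spectrum_id = as.character(seq_len(n)),
        class_label = sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6)),
        raw_prob = round(runif(n), 2)
      )
      if (length(unique(psms$class_label)) < 2) next
      stats <- compute_threshold_stats(psms)
      for (j in seq_len(nrow(stats))) {
        t <- stats$threshold[j]
        expect_equal(stats$tp[j], sum(psms$raw_prob >= t & psms$class_label == 1))
        expect_equal(stats$fp[j], sum(psms$raw_prob >= t & psms$class_label == 0))
        expect_equal(stats$est_fdr[j],
                     brute_fdr(psms$class_label, psms$raw_prob, t))
      }
      # monotone counting as the threshold decreases
      expect_true(all(diff(stats$tp) >= 0))
      expect_true(all(diff(stats$fp) >= 0))
    }
  })
})

test_that("threshold selection maximizes acceptance under the FDR bound", {
  psms <- tibble::tibble(spectrum_id = c("a", "b", "c"),
                         class_label = c(1L, 0L, 1L),
                         raw_prob = c(0.9, 0.8, 0.7))
  stats <- compute_threshold_stats(psms)
  # target 0.6: the 0.7 point (2 targets at FDR 0.5)
  sel <- select_threshold(stats, 0.6)
  expect_equal(sel$threshold, 0.7)
  expect_equal(sel$accepted_targets, 2)
  expect_false(sel$flagged)
  # target below everything achievable: flagged fallback at smallest est_fdr
  hopeless <- compute_threshold_stats(
    tibble::tibble(spectrum_id = c("a", "b"), class_label = c(0L, 1L),
                   raw_prob = c(0.9, 0.8)))
  sel2 <- select_threshold(hopeless, 0.01)
  expect_true(sel2$flagged)
  expect_equal(sel2$threshold, 0.8) # the only point accepting any target
  # all points at est_fdr 0: maximal acceptance, i.e. the lowest threshold
  clean <- tibble::tibble(spectrum_id = letters[1:4],
                          class_label = c(1L, 1L, 1L, 0L),
                          raw_prob = c(0.9, 0.8, 0.7, 0.1))
  sel3 <- select_threshold(compute_threshold_stats(clean), 0.01)
  expect_equal(sel3$threshold, 0.7)
  expect_equal(sel3$accepted_targets, 3)
})

test_that("sensitivity curve equals brute-force maximization and is monotone", {
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- 60
      psms <- tibble::tibble(
        spectrum_id = as.character(seq_len(n)),
        class_label = rep(c(0L, 1L), each = n / 2),
        raw_prob = round(c(runif(n / 2, 0, 0.7), runif(n / 2, 0.2, 1)), 2)
      )
      stats <- compute_threshold_stats(psms)
      grid <- seq(0.01, 0.2, by = 0.01)
      curve <- sensitivity_curve(stats, grid)
      expect_true(all(diff(curve$accepted_targets) >= 0))
      for (j in seq_along(grid)) {
        expect_equal(curve$accepted_targets[j],
                     brute_best_sensitivity(psms$class_label, psms$raw_prob,
                                            grid[j]))
      }
    }
  })
})

test_that("mean sensitivity averages the 1-5% grid", {
  psms <- tibble::tibble(spectrum_id = as.character(1:40),
                         class_label = rep(c(0L, 1L), each = 20),
                         raw_prob = c(runif(20, 0, 0.4), runif(20, 0.5, 1)))
  stats <- compute_threshold_stats(psms)
  curve <- sensitivity_curve(stats)
  expect_equal(mean_sensitivity(stats), mean(curve$accepted_targets))
  # constant curve: perfectly separated data accepts everything at any FDR
  expect_equal(mean_sensitivity(stats), 20)
  # direct arithmetic on a hand-made stats table
  hand <- tibble::tibble(
    threshold = c(0.9, 0.8, 0.7, 0.6, 0.5),
    tp = c(10L, 20L, 30L, 40L, 50L), fp = c(0L, 0L, 0L, 1L, 2L),
    tn = 50L, fn = 0L,
    est_fdr = c(0.005, 0.008, 0.01, 0.025, 0.04),
    accepted_targets = c(10L, 20L, 30L, 40L, 50L)
  )
  expect_equal(mean_sensitivity(hand), mean(c(30, 30, 40, 50, 50)))
})

test_that("null data yields almost no acceptances at 1% FDR", {
  # with no correct targets the decoy estimate should shut the gate
  counts <- vapply(1:10, function(s) {
    sim <- simulate_psms(n_targets = 800, n_decoys = 800, frac_correct = 0,
                         seed = 500 + s)
    fit <- train_cost_ann(sim$psms, cost_matrix(1),
                          ann_hyperparams(epochs = 100, seed = s))
    stats <- compute_threshold_stats(predict_probabilities(fit, sim$psms))
    sensitivity_curve(stats, 0.01)$accepted_targets
  }, numeric(1))
  expect_lte(mean(counts), 0.02 * 800)
})

test_that("threshold statistics export as TSV", {
  psms <- tibble::tibble(spectrum_id = c("a", "b"), class_label = c(1L, 0L),
                         raw_prob = c(0.9, 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_stats(compute_threshold_stats(psms), f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_true(all(c("threshold", "tp", "fp", "est_fdr") %in% names(back)))
})
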