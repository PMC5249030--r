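#' Default score distributions for the synthetic PSM generator
#'
#' Returns the per-score sampling parameters for the two latent populations
#' of a composite target-decoy search: `correct` (true peptide assignments)
#' and `incorrect` (wrong targets and decoys, which share one parameter set
#' — the exchangeability premise of decoy counting). The defaults are
#' engineering choices giving a realistic degree of separation: correct PSMs
#' have a gamma-shifted Xcorr, higher deltaCn and fraction of matched ions,
#' low SpRank, small mass error and small retention-time p-values; the
#' incorrect population has a truncated-Gaussian Xcorr and uninformative
#' mass error and RT p-value.
#'
#' @param phospho_like If `TRUE`, shrink the correct/incorrect separation on
#'   `delta_cn`, emulating the deltaCn suppression seen for multi-site
#'   phosphopeptides.
#' @return A nested list with elements `correct` and `incorrect`, each a
#'   list of per-score parameters. Any entry can be overridden and passed to
#'   [simulate_psms()].
#' @export
default_score_params <- function(phospho_like = FALSE) {
  p <- list(
    correct = list(
      xcorr = list(shape = 8, scale = 0.45, shift = 1.5),
      delta_cn = list(shape1 = 5, shape2 = 15, shift = 0.05),
      perc_ions = list(shape1 = 8, shape2 = 4),
      sp_rank = list(prob = 0.7),
      delta_m = list(sd = 0.01),
      rt_pvalue = list(shape1 = 1, shape2 = 9)
    ),
    incorrect = list(
      xcorr = list(mean = 1.6, sd = 0.4),
      delta_cn = list(shape1 = 1.2, shape2 = 20, shift = 0),
      perc_ions = list(shape1 = 3, shape2 = 8),
      sp_rank = list(prob = 0.15),
      delta_m = list(min = -1.1, max = 1.1),
      rt_pvalue = list(min = 0, max = 1)
    )
  )
  if (phospho_like) {
    p$correct$delta_cn <- list(shape1 = 2, shape2 = 20, shift = 0.02)
  }
  p
}

# sample the six scores for n PSMs of one latent population
sample_scores <- function(n, pop, params) {
  pr <- params[[pop]]
  if (pop == "correct") {
    xcorr <- stats::rgamma(n, shape = pr$xcorr$shape, scale = pr$xcorr$scale) +
      pr$xcorr$shift
    delta_m <- stats::rnorm(n, 0, pr$delta_m$sd)
    rt_pvalue <- stats::rbeta(n, pr$rt_pvalue$shape1, pr$rt_pvalue$shape2)
  } else {
    xcorr <- pmax(stats::rnorm(n, pr$xcorr$mean, pr$xcorr$sd), 0)
    delta_m <- stats::runif(n, pr$delta_m$min, pr$delta_m$max)
    rt_pvalue <- stats::runif(n, pr$rt_pvalue$min, pr$rt_pvalue$max)
  }
  tibble::tibble(
    delta_cn = pmin(pmax(stats::rbeta(n, pr$delta_cn$shape1, pr$delta_cn$shape2) +
                           pr$delta_cn$shift, 0), 1),
    xcorr = xcorr,
    delta_m = delta_m,
    sp_rank = 1 + stats::rgeom(n, pr$sp_rank$prob),
    perc_ions = stats::rbeta(n, pr$perc_ions$shape1, pr$perc_ions$shape2),
    rt_pvalue = rt_pvalue
  )
}

# random tryptic-looking peptide, optionally with a phospho marker on S/T/Y
random_peptides <- function(n, phospho = FALSE, marker = "*") {
  aas <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]]
  peps <- vapply(seq_len(n), function(i) {
    len <- sample(7:18, 1)
    body <- paste(sample(aas, len - 1, replace = TRUE), collapse = "")
    paste0(body, sample(c("K", "R"), 1))
  }, character(1))
  if (phospho) {
    peps <- vapply(peps, function(p) {
      chars <- strsplit(p, "")[[1]]
      sty <- which(chars %in% c("S", "T", "Y"))
      if (length(sty) == 0) {
        pos <- sample(seq_len(nchar(p) - 1), 1)
        chars[pos] <- "S"
        sty <- pos
      }
      site <- if (length(sty) == 1) sty else sample(sty, 1)
      paste0(paste(chars[seq_len(site)], collapse = ""), marker,
             paste(chars[-seq_len(site)], collapse = ""))
    }, character(1))
  }
  unname(peps)
}

#' Simulate a composite target-decoy PSM dataset with hidden ground truth
#'
#' Generates a PSM table with the statistical structure that decoy-counting
#' FDR estimation assumes: a fraction `frac_correct` of target PSMs are
#' drawn from the `correct` score distributions, while the remaining
#' targets and all decoys are drawn i.i.d. from one shared `incorrect`
#' distribution. Which targets are correct is recorded in a ground-truth
#' sidecar, never in the PSM table itself. The defaults (5000 targets, 5000
#' decoys, 15\% correct targets) mirror a typical phospho-enrichment run in
#' which fewer than a fifth of target hits are genuine.
#'
#' @param n_targets,n_decoys Number of target and decoy PSMs (each >= 1).
#' @param frac_correct Fraction of targets that are correct, in \[0,1\];
#'   exactly `round(frac_correct * n_targets)` targets are flagged correct.
#' @param score_params Distribution parameters as produced by
#'   [default_score_params()].
#' @param phospho_like Use the phospho-like preset (reduced deltaCn
#'   separation); ignored when `score_params` is supplied explicitly.
#' @param decoy_prefix Accession prefix given to decoy PSMs.
#' @param phospho_marker Modification marker used in peptide strings when
#'   `phospho_like = TRUE`.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset exactly. `NULL` uses the current RNG state.
#' @return A list with `psms` (canonical PSM tibble, targets first) and
#'   `truth` (tibble `spectrum_id`, `is_correct`; decoys are always
#'   incorrect).
#' @examples
#' sim <- simulate_psms(n_targets = 200, n_decoys = 200, seed = 1)
#' table(sim$psms$class_label)
#' sum(sim$truth$is_correct)
#' @export
simulate_psms <- function(n_targets = 5000, n_decoys = 5000,
                          frac_correct = 0.15,
                          score_params = default_score_params(phospho_like),
                          phospho_like = FALSE,
                          decoy_prefix = "REV_", phospho_marker = "*",
                          seed = NULL) {
  if (frac_correct < 0 || frac_correct > 1) {
    abort("frac_correct must lie in [0, 1]")
  }
  if (n_targets < 1 || n_decoys < 1) abort("n_targets and n_decoys must be >= 1")
  gen <- function() {
    n_correct <- round(frac_correct * n_targets)
    n <- n_targets + n_decoys
    scores <- dplyr::bind_rows(
      sample_scores(n_correct, "correct", score_params),
      sample_scores(n_targets - n_correct, "incorrect", score_params),
      sample_scores(n_decoys, "incorrect", score_params)
    )
    is_correct <- c(rep(TRUE, n_correct), rep(FALSE, n - n_correct))
    label <- c(rep(1L, n_targets), rep(0L, n_decoys))
    psms <- tibble::tibble(
      spectrum_id = sprintf("spec_%06d", seq_len(n)),
      peptide = random_peptides(n, phospho = phospho_like, marker = phospho_marker),
      charge = sample(c(2L, 3L), n, replace = TRUE),
      protein_accession = ifelse(label == 0L,
                                 sprintf("%sP%05d", decoy_prefix, seq_len(n)),
                                 sprintf("P%05d", seq_len(n))),
      class_label = label
    )
    psms <- dplyr::bind_cols(psms, scores)
    list(psms = validate_psms(psms, decoy_prefix),
         truth = tibble::tibble(spectrum_id = psms$spectrum_id,
                                is_correct = is_correct))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' True FDR from ground truth
#'
#' The ground-truth counterpart of the decoy-counting estimate: among target
#' PSMs with probability at or above `threshold`, the fraction whose peptide
#' assignment is actually incorrect. Returns 0 when no targets are accepted.
#'
#' @param psms An annotated PSM table with the chosen probability column set.
#' @param truth Ground-truth sidecar from [simulate_psms()] (`spectrum_id`,
#'   `is_correct`).
#' @param threshold Acceptance threshold (inclusive).
#' @param prob Which probability column to threshold.
#' @return The true false discovery rate among accepted targets.
#' @export
true_fdr <- function(psms, truth, threshold, prob = c("raw_prob", "adjusted_prob")) {
  prob <- match.arg(prob)
  if (!prob %in% names(psms) || anyNA(psms[[prob]])) {
    abort(paste0("probability column '", prob, "' must be set on all records"))
  }
  d <- dplyr::left_join(psms, truth, by = "spectrum_id")
  if (anyNA(d$is_correct)) abort("truth table does not cover all spectra")
  acc <- d$class_label == 1L & d[[prob]] >= threshold
  if (!any(acc)) return(0)
  sum(!d$is_correct[acc]) / sum(acc)
}
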