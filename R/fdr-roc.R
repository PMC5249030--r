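#' Decoy-counting FDR estimate at a threshold
#'
#' Estimates the false discovery rate among accepted target PSMs by decoy
#' counting: with `D_t` decoys and `N_t` total PSMs scoring at or above the
#' threshold `t`, the estimate is `D_t / (N_t - D_t)` — decoys accepted over
#' targets accepted. The threshold comparison is inclusive (`>=`). When no
#' targets are accepted the estimate is 0 if no decoys are accepted either,
#' and is reported as 1 (the capped infinite-rate sentinel) otherwise.
#'
#' @param labels 0/1 class labels (0 = decoy, 1 = target).
#' @param probs Discriminant probabilities in \[0, 1\].
#' @param threshold Acceptance threshold.
#' @return The estimated FDR (non-negative).
#' @examples
#' estimate_fdr(c(0, rep(1, 100)), c(0.9, runif(100, 0.5, 1)), 0.5)
#' @export
estimate_fdr <- function(labels, probs, threshold) {
  if (length(labels) == 0) abort("empty input")
  if (length(labels) != length(probs)) abort("labels and probs differ in length")
  acc <- probs >= threshold
  d_t <- sum(acc & labels == 0)
  tp <- sum(acc & labels == 1)
  if (tp == 0) {
    if (d_t == 0) return(0)
    return(1)
  }
  d_t / tp
}

#' Threshold statistics along the ROC sweep
#'
#' Computes one operating point per distinct probability value, sorted by
#' decreasing threshold, plus a sentinel point just above the maximum at
#' which nothing is accepted. At each threshold `t` the point records the
#' accepted targets (`tp`), accepted decoys (`fp`), the complements `tn`
#' and `fn`, and the decoy-counting FDR estimate `est_fdr = fp / tp`
#' (conventions as in [estimate_fdr()]).
#'
#' @param psms A PSM table with `class_label` and the chosen probability
#'   column set on every record.
#' @param prob Name of the probability column to sweep.
#' @return A tibble with columns `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `est_fdr`, `accepted_targets` (`= tp`), ordered by decreasing
#'   threshold.
#' @export
compute_threshold_stats <- function(psms, prob = "raw_prob") {
  if (!prob %in% names(psms) || anyNA(psms[[prob]])) {
    abort(paste0("probability column '", prob, "' must be set on all records"))
  }
  p <- psms[[prob]]
  lab <- psms$class_label
  n1 <- sum(lab == 1L)
  n0 <- sum(lab == 0L)
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  ls <- lab[ord]
  last <- !duplicated(ps, fromLast = FALSE) # first index of each distinct value
  # cumulative accepted counts at each distinct threshold (inclusive >=)
  cum_tp <- cumsum(ls == 1L)
  cum_fp <- cumsum(ls == 0L)
  idx <- which(c(last[-1], TRUE)) # last occurrence of each distinct value
  thr <- ps[idx]
  tp <- cum_tp[idx]
  fp <- cum_fp[idx]
  stats <- tibble::tibble(
    threshold = c(max(ps) + 1e-9, thr),
    tp = c(0L, tp), fp = c(0L, fp)
  ) %>%
    dplyr::mutate(
      tn = n0 - .data$fp, fn = n1 - .data$tp,
      est_fdr = dplyr::case_when(
        .data$tp > 0 ~ .data$fp / .data$tp,
        .data$fp > 0 ~ 1,
        TRUE ~ 0
      ),
      accepted_targets = .data$tp
    )
  stats
}

#' Select the operating point for a target FDR
#'
#' Returns the operating point that maximizes the number of accepted target
#' PSMs among all points with estimated FDR at or below `target_fdr`; ties
#' are broken toward the higher threshold. When no point qualifies, the
#' point with the smallest estimated FDR is returned with `flagged = TRUE`.
#'
#' Qualification requires a non-empty acceptance (`tp > 0`): the sentinel
#' "accept nothing" point has estimated FDR 0 by convention but is not a
#' usable operating point.
#'
#' @param stats Threshold statistics from [compute_threshold_stats()].
#' @param target_fdr Desired FDR, in (0, 1); 1\% is the usual
#'   sensitivity/precision trade-off.
#' @return A one-row tibble: the chosen operating point plus a `flagged`
#'   logical column.
#' @export
select_threshold <- function(stats, target_fdr = 0.01) {
  if (nrow(stats) == 0) abort("no threshold statistics supplied")
  usable <- stats[stats$accepted_targets > 0, ]
  if (nrow(usable) == 0) {
    out <- stats[order(-stats$threshold), ][1, ]
    out$flagged <- TRUE
    return(out)
  }
  ok <- usable$est_fdr <= target_fdr
  if (any(ok)) {
    cand <- usable[ok, ]
    cand <- cand[order(-cand$accepted_targets, -cand$threshold), ]
    out <- cand[1, ]
    out$flagged <- FALSE
  } else {
    cand <- usable[order(usable$est_fdr, -usable$accepted_targets, -usable$threshold), ]
    out <- cand[1, ]
    out$flagged <- TRUE
  }
  out
}

#' Sensitivity curve: accepted PSMs versus estimated FDR
#'
#' For each FDR on the grid, the maximum number of target PSMs acceptable
#' at an estimated FDR no larger than that value (0 when no operating point
#' qualifies). The curve is non-decreasing in FDR.
#'
#' @param stats Threshold statistics from [compute_threshold_stats()].
#' @param fdr_grid FDR values, by default 1\% through 5\%.
#' @return A tibble `fdr`, `accepted_targets`, `threshold` (NA when no
#'   point qualifies at that FDR).
#' @export
sensitivity_curve <- function(stats, fdr_grid = seq(0.01, 0.05, by = 0.01)) {
  purrr::map_dfr(fdr_grid, function(f) {
    ok <- stats$est_fdr <= f & stats$accepted_targets > 0
    if (!any(ok)) {
      return(tibble::tibble(fdr = f, accepted_targets = 0L, threshold = NA_real_))
    }
    sel <- select_threshold(stats, f)
    tibble::tibble(fdr = f, accepted_targets = as.integer(sel$accepted_targets),
                   threshold = sel$threshold)
  })
}

#' Mean sensitivity over the 1-5% FDR grid
#'
#' The model-selection score of the cost sweep: the average number of
#' accepted target PSMs over estimated FDRs of 1, 2, 3, 4 and 5\%.
#'
#' @inheritParams sensitivity_curve
#' @return A single number.
#' @export
mean_sensitivity <- function(stats, fdr_grid = seq(0.01, 0.05, by = 0.01)) {
  if (nrow(stats) == 0) abort("no threshold statistics supplied")
  mean(sensitivity_curve(stats, fdr_grid)$accepted_targets)
}

#' Export threshold statistics or a sensitivity curve as TSV
#'
#' @param x A tibble from [compute_threshold_stats()] or
#'   [sensitivity_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_stats <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
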