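#' Plot the sensitivity curve of a rescoring run
#'
#' Accepted target PSMs versus estimated FDR for the winning model, with
#' the per-cost mean sensitivities inset as a caption.
#'
#' @param object A `psm_rescoring` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psm_rescoring <- function(object, ...) {
  curve <- object$sensitivity_curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fdr, y = .data$accepted_targets)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(
      x = "estimated FDR",
      y = "accepted target PSMs",
      title = sprintf("Sensitivity at 1-5%% FDR (best CFP = %d)", object$best_cfp)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' deltaCn vs Xcorr relabeling scatter
#'
#' The diagnostic scatter of the two primary search scores, colored by
#' class, before (target/decoy labels) and after (predicted classes)
#' rescoring. After rescoring, the dense low-score cloud — the mixture of
#' decoys and wrong targets — should turn almost entirely class 0.
#'
#' @param psms An annotated PSM table with `predicted_class` set.
#' @return A ggplot with before/after facets.
#' @export
plot_relabeling <- function(psms) {
  psms <- tibble::as_tibble(psms)
  if (!"predicted_class" %in% names(psms) || anyNA(psms$predicted_class)) {
    abort("predicted_class must be set; run rescore_psms() first")
  }
  long <- dplyr::bind_rows(
    dplyr::mutate(psms, panel = "before (target/decoy label)",
                  class = factor(.data$class_label)),
    dplyr::mutate(psms, panel = "after (predicted class)",
                  class = factor(.data$predicted_class))
  ) %>%
    dplyr::mutate(panel = factor(.data$panel, levels = c(
      "before (target/decoy label)", "after (predicted class)")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$xcorr, y = .data$delta_cn,
                                     colour = .data$class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_colour_manual(values = c(`0` = "#3366BB", `1` = "#CC3333"),
                                 name = "class") +
    ggplot2::labs(x = "Xcorr", y = "deltaCn") +
    ggplot2::theme_minimal()
}

#' Plot the decoy-counting ROC sweep
#'
#' Operating points of the probability sweep as a conventional ROC curve
#' (decoy acceptance rate vs target acceptance rate), with points at or
#' below the target FDR highlighted.
#'
#' @param stats Threshold statistics from [compute_threshold_stats()].
#' @param target_fdr FDR used for highlighting (default 1\%).
#' @return A ggplot.
#' @export
plot_threshold_stats <- function(stats, target_fdr = 0.01) {
  df <- dplyr::mutate(stats,
                      fpr = .data$fp / (.data$fp + .data$tn),
                      tpr = .data$tp / (.data$tp + .data$fn),
                      within = .data$est_fdr <= target_fdr & .data$tp > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$within), size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#228833", `FALSE` = "grey60"),
      name = sprintf("est. FDR <= %g%%", 100 * target_fdr)) +
    ggplot2::labs(x = "decoys accepted (rate)", y = "targets accepted (rate)") +
    ggplot2::theme_minimal()
}
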