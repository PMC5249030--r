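#' Confusion matrix of 0/1 predictions
#'
#' Rows are actual classes, columns predicted classes, in the order 0 then
#' 1, i.e. `[[TN, FP], [FN, TP]]`.
#'
#' @param actual,predicted Equal-length 0/1 label vectors.
#' @return A 2x2 integer matrix with dimnames `actual` x `predicted`.
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 0, 1))
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("actual and predicted differ in length")
  }
  if (!all(actual %in% 0:1) || !all(predicted %in% 0:1)) {
    abort("labels must be 0 or 1")
  }
  m <- matrix(0L, 2, 2, dimnames = list(actual = c("0", "1"),
                                        predicted = c("0", "1")))
  tab <- table(factor(actual, levels = 0:1), factor(predicted, levels = 0:1))
  m[] <- as.integer(tab)
  m
}

# half-up decimal rounding (matches how report tables are printed)
round_half_up <- function(x, digits = 4) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Classical metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`. A metric with a zero denominator
#' is undefined and reported as `NA`, never 0.
#'
#' @param cm A 2x2 confusion matrix as from [confusion_matrix()]
#'   (`[[TN, FP], [FN, TP]]`).
#' @param digits Round the metrics half-up to this many decimals;
#'   `NULL` for unrounded values.
#' @return A one-row tibble `accuracy`, `sensitivity`, `specificity`,
#'   `precision`.
#' @examples
#' cm <- matrix(c(8904L, 12L, 13L, 1047L), 2, 2, byrow = TRUE)
#' classification_metrics(cm) # the printed worked example
#' @export
classification_metrics <- function(cm, digits = NULL) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2))) abort("cm must be a 2x2 matrix")
  if (any(cm < 0)) abort("cm entries must be non-negative")
  n <- sum(cm)
  if (n == 0) abort("confusion matrix is all zero")
  tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- tibble::tibble(
    accuracy = (tp + tn) / n,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp)
  )
  if (!is.null(digits)) out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ round_half_up(.x, digits)))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over all distinct score thresholds, with tied scores
#' grouped into single operating points. Equals the Mann-Whitney
#' probability that a random positive outscores a random negative (ties
#' counting one half).
#'
#' @param labels 0/1 truth labels; both classes must be present.
#' @param probs Scores (higher = more positive).
#' @return The AUC, in \[0, 1\].
#' @export
roc_auc <- function(labels, probs) {
  if (length(labels) != length(probs)) abort("labels and probs differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  # trapezoid over distinct thresholds, descending
  ord <- order(probs, decreasing = TRUE)
  ls <- labels[ord]
  ps <- probs[ord]
  grp_last <- which(c(ps[-length(ps)] != ps[-1], TRUE))
  tpr <- c(0, cumsum(ls == 1)[grp_last] / n1)
  fpr <- c(0, cumsum(ls == 0)[grp_last] / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Known-protein truth labels
#'
#' For evaluation against a sample of known content: a target PSM counts as
#' a true positive when its protein accession (or, in `"peptide"` mode, its
#' peptide string) appears in the supplied reference list.
#'
#' @param psms A PSM table.
#' @param known Character vector of known protein accessions (or peptide
#'   strings in `"peptide"` mode).
#' @param mode Match on `"accession"` (default) or `"peptide"`.
#' @return An integer 0/1 vector, one entry per PSM.
#' @export
known_protein_labels <- function(psms, known, mode = c("accession", "peptide")) {
  mode <- match.arg(mode)
  key <- if (mode == "accession") psms$protein_accession else psms$peptide
  as.integer(key %in% known)
}

#' Summarize class relabeling after rescoring
#'
#' Counts how the model re-assigned the target-decoy labels: targets
#' predicted class 0 (the relabeled, presumed-wrong targets), targets kept
#' in class 1, and decoys predicted in either class. These are the numbers
#' shown beside the deltaCn-vs-Xcorr relabeling scatter.
#'
#' @param before A PSM table carrying `class_label`; when `after` is `NULL`
#'   it must also carry `predicted_class`.
#' @param after Optional second table carrying `predicted_class` for the
#'   same spectra (matched by `spectrum_id`).
#' @return A one-row tibble `targets_to_class0`, `targets_kept_class1`,
#'   `decoys_to_class1`, `decoys_kept_class0`.
#' @export
relabeling_summary <- function(before, after = NULL) {
  before <- tibble::as_tibble(before)
  if (is.null(after)) {
    joined <- before
  } else {
    after <- tibble::as_tibble(after)
    if (!setequal(before$spectrum_id, after$spectrum_id)) {
      abort("before and after tables cover different spectra")
    }
    joined <- dplyr::left_join(
      dplyr::select(before, "spectrum_id", "class_label"),
      dplyr::select(after, "spectrum_id", "predicted_class"),
      by = "spectrum_id")
  }
  if (!"predicted_class" %in% names(joined) || anyNA(joined$predicted_class)) {
    abort("predicted_class must be set on all records")
  }
  tibble::tibble(
    targets_to_class0 = sum(joined$class_label == 1L & joined$predicted_class == 0L),
    targets_kept_class1 = sum(joined$class_label == 1L & joined$predicted_class == 1L),
    decoys_to_class1 = sum(joined$class_label == 0L & joined$predicted_class == 1L),
    decoys_kept_class0 = sum(joined$class_label == 0L & joined$predicted_class == 0L)
  )
}

#' Evaluation report against known ground truth
#'
#' Bundles the post-hoc assessment of a rescoring run when the sample
#' content is known: the prediction confusion matrix against the
#' known-protein truth, the four classical metrics, the AUC of the adjusted
#' probabilities against that truth, and the relabeling counts. Written as
#' JSON when `path` is given.
#'
#' @param result A `psm_rescoring` object.
#' @param truth_labels 0/1 truth per PSM of `result$psms` (e.g. from
#'   [known_protein_labels()] or a simulation ground-truth sidecar).
#' @param path Optional JSON output path.
#' @return A list with `confusion`, `metrics`, `auc`, `relabeling`.
#' @export
evaluation_report <- function(result, truth_labels, path = NULL) {
  stopifnot(inherits(result, "psm_rescoring"))
  psms <- result$psms
  cm <- confusion_matrix(truth_labels, psms$predicted_class)
  out <- list(
    confusion = cm,
    metrics = classification_metrics(cm, digits = 4),
    auc = roc_auc(truth_labels, psms$adjusted_prob),
    relabeling = relabeling_summary(psms)
  )
  if (!is.null(path)) {
    jsonlite::write_json(list(
      format = "psmrescore-evaluation", version = 1L,
      confusion = unclass(out$confusion), metrics = out$metrics,
      auc = out$auc, relabeling = out$relabeling
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
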