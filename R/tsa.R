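#' Threshold-selector probability range correction
#'
#' Re-maps discriminant probabilities so that the chosen FDR threshold sits
#' at the conventional decision point 0.5 and the observed range spans
#' \[0, 1\]: values equal to the threshold become exactly 0.5, the observed
#' minimum maps to 0, the observed maximum maps to 1, and the two segments
#' in between are stretched linearly. This is the unique continuous
#' piecewise-linear map through the three anchors, so the rank order of
#' distinct values — and therefore any ROC curve computed on them — is
#' preserved, and the accepted set `{adjusted >= 0.5}` is exactly
#' `{raw >= threshold}`.
#'
#' When the threshold coincides with the observed minimum (or maximum) the
#' corresponding segment is degenerate and maps constantly to 0.5, so that
#' endpoint cannot also reach its 0 (or 1) anchor; a warning is emitted.
#' Values outside the fitted range (e.g., future data scored with a stored
#' map) are mapped by the nearer segment's line and clipped to \[0, 1\].
#'
#' @param probs Probabilities in \[0, 1\]; non-empty.
#' @param threshold The selected raw-probability threshold, inside
#'   `[min(probs), max(probs)]`.
#' @return Adjusted probabilities in \[0, 1\], same length and order.
#' @examples
#' adjust_probabilities(c(0.2, 0.4, 0.6, 0.8), 0.6) # 0, 0.25, 0.5, 1
#' @export
adjust_probabilities <- function(probs, threshold) {
  if (length(probs) == 0) abort("probs must be non-empty")
  if (anyNA(probs)) abort("probs must not contain NA")
  if (any(probs < 0 | probs > 1)) abort("probs must lie in [0, 1]")
  lo <- min(probs)
  hi <- max(probs)
  if (threshold < lo || threshold > hi) {
    abort(sprintf("threshold %g outside the observed range [%g, %g]",
                  threshold, lo, hi))
  }
  if (threshold == lo) {
    warn("threshold equals the observed minimum; lower segment is degenerate")
  }
  if (threshold == hi) {
    warn("threshold equals the observed maximum; upper segment is degenerate")
  }
  below <- probs < threshold
  out <- numeric(length(probs))
  if (threshold > lo) {
    out[below] <- 0.5 * (probs[below] - lo) / (threshold - lo)
  } else {
    out[below] <- 0.5 # degenerate lower segment (empty in-range anyway)
  }
  if (hi > threshold) {
    out[!below] <- 0.5 + 0.5 * (probs[!below] - threshold) / (hi - threshold)
  } else {
    out[!below] <- 0.5
  }
  pmin(pmax(out, 0), 1)
}
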