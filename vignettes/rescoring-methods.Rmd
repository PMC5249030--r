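---
title: "Cost-sensitive target-decoy rescoring: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive target-decoy rescoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A shotgun-proteomics run produces thousands of MS/MS spectra; a database
search engine (Sequest-style) assigns each spectrum its best-matching
peptide, yielding one peptide-spectrum match (PSM) per spectrum. Most of
these assignments are wrong — typically fewer than 20% of target PSMs are
correct — so the accepted set must be chosen to control the false discovery
rate (FDR). Searching a composite target-decoy database (targets plus
reversed protein sequences) provides the error model: a wrong PSM is
equally likely to hit a target or a decoy sequence, so decoy hits, which
are wrong by construction, are statistical stand-ins for the wrong target
hits. With `D_t` decoys and `N_t` PSMs in total scoring at or above a
threshold `t`, the FDR among accepted targets is estimated as

    FDR(t) = D_t / (N_t - D_t)

The naive approach thresholds one or two scores. This package instead
combines six scores per PSM — deltaCn, Xcorr, deltaM, SpRank, the fraction
of matched fragment ions, and a retention-time p-value — through a small
neural network, and selects the network-probability threshold that meets
the desired FDR with the most accepted PSMs.

## The cost-sensitive network

The classifier is a feed-forward network with six inputs, one hidden layer
(4 sigmoid nodes by default) and a single sigmoid output in (0, 1). It is
trained on the dataset being analyzed itself: decoys are class 0, targets
class 1. This labeling is deliberately noisy — most targets are really
class-0 material — and that is where the cost matrix comes in. Only the
decoy labels are trustworthy, so misclassifying a decoy (a false positive)
costs `CFP >= 1` while misclassifying a target costs `CFN = 1`. Raising
`CFP` biases the decision boundary toward class 0, which "relabels" the
wrong targets sitting in the decoy cloud and sharpens the boundary between
correct and incorrect PSMs. Since no single `CFP` suits every dataset, the
pipeline trains one model per integer `CFP` in 1..10 and keeps the one with
the highest mean number of PSMs accepted at estimated FDRs of 1–5% (ties go
to the smaller cost). The `CFP = 1` model is the unweighted baseline, so
the sweep can never select something worse than it.

### Training regime and numerical choices

The underlying toolkit of the original method does not pin down a loss,
batch regime, or initialization, so these are this package's own choices:

* **Cost realization.** Instance reweighting of the loss: class-0 records
  weigh `cfp`, class-1 records `cfn`. Reweighting (rather than
  minimum-expected-cost prediction) keeps the continuous output that the
  ROC sweep needs, and satisfies an exact contract: training with integer
  weight `w` is identical to training with the record replicated `w` times.
* **Loss and optimizer.** Weight-normalized mean squared error with sigmoid
  activations, minimized by full-batch gradient descent with classical
  momentum: one weight update per epoch, for exactly `epochs` epochs
  (default 1000, learning rate 0.3, momentum 0.2). A per-epoch shuffle
  would have no effect in full-batch mode, so none is performed; this makes
  the replication contract exact and determinism trivial.
* **Standardization.** Each score is affinely mapped to [-1, 1] by its
  min/max over the training data; the map is stored in the model and reused
  at prediction time.
* **Initialization.** Weights and biases uniform on [-0.5, 0.5] from a
  seeded generator; everything downstream is deterministic given the seed.
  Each cost in the sweep uses the same seed, so the sweep isolates the
  effect of the cost matrix.
* **Floors.** Network outputs are clipped to [1e-9, 1 - 1e-9], so they are
  strictly inside (0, 1) even for extreme inputs.

Full-batch descent at these rates needs several hundred epochs to move far
from initialization; with few epochs (say, below ~200 at 10,000 records)
the sweep may select a barely trained model. The default 1000 epochs is
also what the downstream calibration was validated with.

## The ROC sweep and threshold selection

After scoring, every distinct probability value is an operating point: at
threshold `t` (inclusive, `>=`), `tp` targets and `fp` decoys are accepted
and `est_fdr = fp / tp`. Conventions: a point accepting no targets has
`est_fdr = 0` if it accepts no decoys, and the capped sentinel value 1
otherwise; a sentinel point just above the maximum probability represents
"accept nothing". Estimates are deliberately **not** monotonized into
q-values — the procedure is raw decoy counting per threshold, and
monotonization would change the reported counts.

The operating point for a target FDR (default 1%, the usual
sensitivity/precision trade-off) is the one maximizing accepted targets
among points with `est_fdr` at or below the target, ties broken toward the
higher threshold; the "accept nothing" sentinel never qualifies. When no
point with a non-empty acceptance qualifies, the point with the smallest
estimated FDR is returned and flagged. The sensitivity curve reports, for
each FDR on a grid, the maximum acceptance under that bound (0 when
nothing qualifies), which makes it non-decreasing by construction; the
model-selection score is its mean over the five integer-percent FDRs 1–5%.

## Probability range correction

The raw network output separates targets from decoys, not correct from
incorrect PSMs, so its absolute value is a poor per-PSM correctness
probability (its target/decoy AUC is barely above chance). The
threshold-selector correction re-maps the probabilities so that they can be
consumed individually, e.g. by probability-aware protein inference: values
equal to the selected threshold become exactly 0.5, the observed minimum
maps to 0, the observed maximum to 1, and the two segments in between are
stretched linearly. The published description fixes only the three anchors
("expands" the rest); the two-segment linear map is the unique continuous
piecewise-linear interpolation through them, and it is order-preserving, so
ROC curves and AUC are unchanged and `{adjusted >= 0.5}` is exactly
`{raw >= t}` — the reported identification set is invariant. Degenerate
cases (threshold equal to the observed minimum or maximum) collapse that
segment to the constant 0.5 with a warning; out-of-range values scored
through a stored map are extrapolated by the nearer segment and clipped to
[0, 1].

The final model is the already-trained best-cost model assembled with the
saved threshold — it is not retrained, since retraining from a fresh
initialization could invalidate the saved threshold. Decoys receive
adjusted probabilities too (useful for auditing), but reported
identifications are the class-1 targets only.

## The synthetic generator

Real benchmark runs for this problem are not publicly deposited, so the
package ships a generator that reproduces the statistical structure the
method assumes, with hidden ground truth, making every downstream stage
testable:

* exactly `round(frac_correct * n_targets)` targets are drawn from a
  "correct" score population; the remaining targets and all decoys are
  drawn i.i.d. from one shared "incorrect" population — the decoy-counting
  premise (incorrect targets and decoys exchangeable) holds by
  construction;
* the default populations are: correct — `xcorr ~ gamma(8, 0.45) + 1.5`,
  `delta_cn ~ Beta(5, 15) + 0.05` (clipped to [0, 1]),
  `perc_ions ~ Beta(8, 4)`, `sp_rank ~ 1 + Geom(0.7)`,
  `delta_m ~ N(0, 0.01 Da)` (about 5 ppm of a 2 kDa precursor),
  `rt_pvalue ~ Beta(1, 9)`; incorrect — `xcorr ~ N(1.6, 0.4)` truncated at
  0, `delta_cn ~ Beta(1.2, 20)`, `perc_ions ~ Beta(3, 8)`,
  `sp_rank ~ 1 + Geom(0.15)`, `delta_m ~ U(-1.1, 1.1) Da`,
  `rt_pvalue ~ U(0, 1)`. All of these are engineering defaults chosen once
  for realism (a clear but imperfect separation), not fitted to any real
  search output;
* the default composition, 5000 targets and 5000 decoys with 15% of
  targets correct, reflects a typical phospho-enrichment run where fewer
  than a fifth of target hits are genuine;
* a phospho-like preset shrinks the deltaCn separation
  (`Beta(2, 20) + 0.02` for correct PSMs), emulating the deltaCn
  suppression of multi-site phosphopeptides;
* charge is sampled from {2, 3} and peptide strings are random
  tryptic-looking sequences — plumbing for stratification and overlap
  counting, with no spectral meaning.

What the generator does **not** emulate: correlations between scores
within a PSM, charge- and length-dependent score distributions, retention
time as an actual chromatographic model, spectrum-level effects, or the
shape of real Sequest score distributions. Consequently, passing
calibration tests on this generator shows the estimator and pipeline are
correct *under the exchangeability premise*; it does not certify FDR
accuracy on any particular real dataset. A further consequence is that the
cost sweep rarely beats its `CFP = 1` baseline here: with independent,
cleanly-specified score distributions the unweighted model already finds
the boundary, whereas the cost bias pays off on the messier, suppressed
score distributions of real phospho data. The sweep's guarantee — never
worse than the baseline — is asserted; strict improvement is not.

## Study sizes used by the tests

The shipped suite validates calibration with ten seeded replicates of the
default preset (5000 targets, 5000 decoys, 15% correct), asserting that the
decoy estimate at the selected 1% operating point deviates from the hidden
true FDR by at most 2 percentage points on average, with at least 200
targets accepted per run. Unit tests run on much smaller datasets (tens to
hundreds of records) with reduced epochs; those sizes exercise contracts,
not calibration.

## Known limitations

* One (best) hit per spectrum is assumed; lower-rank search hits are out of
  scope.
* FDR estimates are raw per-threshold counts, so reading them as q-values
  requires external monotonization.
* The known-protein evaluation matches on protein accession (or peptide
  string, configurable); it does not perform protein inference.
* The retention-time p-value is consumed, never computed; upstream tools
  must supply it.
* Strata with very few target PSMs (default fewer than 10) are flagged
  rather than modeled; the network is not trustworthy there.
```{r, eval = FALSE}
library(psmrescore)
sim <- simulate_psms(seed = 1)
res <- rescore_psms(sim$psms, ann_hyperparams(seed = 1))
glance(res)
autoplot(res)
plot_relabeling(res$psms)
```
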