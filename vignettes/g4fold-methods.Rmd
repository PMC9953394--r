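---
title: "Predicting in vivo G-quadruplex formation from chromatin accessibility and sequence"
author: "g4fold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in vivo G-quadruplex formation from chromatin accessibility and sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

G-quadruplexes (G4s) are four-stranded structures that fold in guanine-rich
DNA. In vitro sequencing assays (G4-seq) find on the order of 700,000
candidate G4 sites in the human genome, but antibody-based in vivo assays
(G4 ChIP-seq, G4 CUT&Tag) find only about 10,000 per cell line: whether a
candidate actually folds in a living cell depends on the cellular
environment, above all on chromatin accessibility. `g4fold` treats this as
a supervised, cell-type-specific classification problem: given a candidate
interval, a chromatin-accessibility signal track (ATAC-seq) and the
reference sequence, predict whether the candidate folds in vivo in that
cell type.

The resulting dataset is extremely skewed (roughly 1 positive per 100
negatives genome-wide), which drives most of the design below: oversampled
training, untouched test sets, and precision-recall-centred evaluation.

## Labeling candidates

A candidate is *active* when its overlap with an in vivo peak reaches a
fraction of a reference length:

* `overlap_fraction` — default **0.10**.
* `fraction_of` — which length the fraction applies to. The default is the
  **peak** length; the candidate's own length is available as an option.
  Both readings exist in the field because peak-calling resolution
  (~100–500 bp) and candidate length (tens of bp) differ by an order of
  magnitude; we default to the peak-relative reading and keep the other
  one a configuration switch rather than guessing it away.
* The comparison is inclusive (`>=`), so an overlap exactly at the
  threshold is a positive; ties at a boundary should not silently flip
  with floating-point noise.
* Aggregation is per-peak: one sufficient peak makes a positive. A
  `summed` mode (total overlap across peaks against a candidate-relative
  threshold) exists for sensitivity analyses; a summed peak-relative
  threshold is rejected as ill-defined.
* Strand is ignored, matching standard interval intersection on
  unstranded peaks.

## Features

Each candidate is reduced to a fixed 2,200-element vector from a 2 kb
window anchored at the candidate's **center** (floor midpoint for
odd-length intervals — the convention has to be fixed somewhere, and the
floor is the 0-based-coordinate-friendly choice):

* **Accessibility block (200 columns).** The window is cut into 200
  non-overlapping 10 bp bins; each feature is the arithmetic mean of the
  per-base signal in the bin, with unstored positions reading as 0. Means
  are taken over the per-base expansion, not coverage-weighted block
  means, so partially covered bins behave identically whichever backend
  (bigWig or bedGraph) supplied the track.
* **Sequence block (2,000 columns).** Each base maps ordinally:
  A→0, T→1, C→2, G→3, anything else (N, ambiguity codes,
  out-of-chromosome padding) → 4. The codes are *category identifiers*,
  not magnitudes: the block is flagged categorical in the feature schema
  and consumed as unordered categories by the classifier. One-hot
  encoding is deliberately avoided — in tree learners it fragments splits
  across thousands of near-empty indicator columns.
* **Strand orientation** (`strand_orient = TRUE` by default):
  minus-strand candidates have their sequence reverse-complemented and
  their accessibility vector reversed, so G-tract patterns read in a
  consistent direction. Whether to orient is genuinely open (unstranded
  peaks dominate real inputs); the flag is recorded in the model schema
  so a model trained one way refuses features built the other way.
* Windows that run past a chromosome end are padded (N / signal 0) with a
  warning instead of erroring, so candidates near chromosome edges keep
  the fixed vector length.

## Classifier

A gradient-boosted decision tree ensemble (binary log-loss, histogram
splits, leaf-wise growth) with the sequence columns declared categorical:
at each split the backend orders the observed categories by gradient
statistics and searches category *partitions*, never one-hot `==`
contrasts (`max_cat_to_onehot = 1`).

Defaults (all overridable through `gbdt_params()`):

| parameter           | default | meaning                                   |
|---------------------|---------|-------------------------------------------|
| `n_estimators`      | 500     | boosting rounds                           |
| `learning_rate`     | 0.1     | shrinkage per round                       |
| `num_leaves`        | 31      | maximum leaves per tree                   |
| `min_child_samples` | 20      | ~minimum samples per leaf (via hessian)   |
| `subsample`         | 0.8     | row fraction per round                    |
| `colsample_bytree`  | 0.8     | column fraction per tree                  |

The stochastic fractions deserve a note, because they are not cosmetic.
After oversampling, the minority class consists largely of duplicated
rows; a fully deterministic booster then grows essentially identical
trees, and when the two classes are separable with a margin, every tree
places its threshold at the same histogram bin edge — which sits at the
*training* positives' boundary, because the quantile sketch puts no cut
points inside an empty margin. Test positives just beyond that boundary
are misranked wholesale. Row/column subsampling decorrelates the trees so
the ensemble averages over threshold placements; this is ordinary
stochastic gradient boosting, and we adopt it as the default rather than
an option.

Training is bit-reproducible given the data, hyperparameters, seed and a
single thread (the default); requesting more threads logs that
reproducibility is relinquished. Models persist as a UBJSON booster plus
a JSON sidecar with the feature schema (column count, categorical flags,
feature mode, strand orientation) and provenance (seed,
hyperparameters); prediction rejects matrices whose schema differs from
the training schema.

## Evaluation protocol

* **One-cell-line experiment**: stratified random half-split (per class,
  the training half takes `floor(n/2)`, the test half the remainder —
  the only rounding convention consistent with odd class counts splitting
  as, e.g., 2491 → 1245/1246), oversampling of the **training half
  only**, training, scoring of the untouched test half.
* **Cross-cell-line experiment**: the entire training cell line is
  oversampled (no split) and the entire test cell line is scored.
* **Oversampling** duplicates uniformly-with-replacement sampled positive
  rows until the class counts are exactly equal. No synthetic feature
  values are created — this is duplication, not SMOTE — and every
  original row stays present.
* **Metrics**: accuracy, precision, recall, F1 at a score threshold
  (default 0.5, ties-to-positive, i.e. `score >= t`); AUROC as the
  tie-aware rank statistic (identical to the trapezoidal area under the
  tie-grouped ROC); average precision as the step sum
  `sum((R_n - R_{n-1}) P_n)` over distinct score cutoffs — explicitly
  *not* the PR trapezoid, which differs under coarse score grids.
  Precision, recall or F1 whose denominator is zero are reported as
  `NaN`, never silently 0: on skewed test sets an all-negative predictor
  has *undefined* precision, and hiding that as 0 misorders model
  comparisons.
* **Repeats**: `repeated_evaluation()` reruns a seeded protocol closure
  with seeds `base_seed .. base_seed + k - 1` (default `k = 5`) and
  reports mean ± standard error (`sd / sqrt(k)`). Both the split and the
  trainer are reseeded each run.

All randomness flows through explicitly passed integer seeds; the
experiment drivers derive their internal seeds (`seed`, `seed + 1`,
`seed + 2` for split, oversampling and training) so a single integer
reproduces a run end to end.

## The synthetic study generator

`generate_synthetic_study()` builds a miniature study on disk — FASTA
genome, candidate BED, bedGraph accessibility track, in vivo peak BED,
and a truth table — with defaults chosen once to mirror the shape of real
whole-genome candidate sets at desk scale:

* 2 chromosomes × 2.6 Mb, 2,000 planted candidates, **1% active**
  (matching the ~1:100 skew of real cell-line candidate pools);
* candidates are G4-like motifs (four G3-runs, 1–7 bp A/C/T loops) with
  *identical* motif structure for active and inactive candidates: the
  planted signal travels through accessibility only, so sequence-only
  models have a known (chance-level) answer and feature-ablation tests
  have ground truth;
* the accessibility track is half-normal background noise
  (sd 0.25 in 50 bp blocks) plus a Gaussian bump (height 4, sd 150 bp)
  at each active candidate;
* in vivo peaks are ~100 bp intervals centered on active candidates —
  wide enough that default labeling recovers the planted truth exactly,
  narrow enough to stay at the resolution limit of peak-grade data;
* candidate spacing guarantees that no 2 kb feature window sees a
  neighbouring candidate's bump.

The truth table is written to its own TSV that no pipeline command ever
reads, so label leakage is structurally impossible. A manifest (config +
seed) makes every study byte-reproducible.

What the generator does *not* emulate: fragment-level ATAC noise and
nucleosome structure, mappability artifacts, sequence-dependent folding
propensity, peak-calling errors, and overlapping/duplicated candidates.
Passing the recovery tests therefore demonstrates that the pipeline's
plumbing and learning machinery recover a planted accessibility signal
under realistic skew — not that real-data performance will match.

## Problem sizes in the test suite

The bundled tests run the full protocol on the default 2,000-candidate
study (once with the planted signal, once with a zero-height control) and
on ~400-candidate fixtures for the experiment drivers; property suites
use 500×50 random interval sets and exhaustively enumerated label
vectors up to length 6. These sizes keep the whole suite in the
minutes range on a single CPU while leaving every contract exercised at
full feature dimensionality (2,200 columns).

## Known limitations

* The GBDT backend is xgboost; the categorical-partition behaviour it
  shares with LightGBM is what the method requires, but regularisation
  details (category smoothing) differ, so numeric scores are not
  comparable across backends.
* Published real-data performance requires the original GEO/ENCODE
  datasets, which this package documents but does not download; nothing
  in the test suite claims to reproduce those headline numbers.
* `min_child_samples` is enforced through the hessian weight, which for
  binary log-loss approximates, rather than equals, a sample count.
* The labeling stage performs no merging of duplicated or overlapping
  candidates; if the input BED contains them, they are labeled (and
  scored) independently.
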