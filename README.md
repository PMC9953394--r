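# g4fold

Cell-type-specific prediction of in vivo G-quadruplex (G4) formation.

## The problem

In vitro sequencing (G4-seq) finds ~700,000 candidate G4 sites in the
human genome; antibody-based in vivo assays (G4 ChIP-seq, G4 CUT&Tag)
find only ~10,000 per cell line. Which candidates actually fold in a
living cell is governed largely by the chromatin environment. `g4fold`
frames this as supervised classification under extreme class skew
(~1 positive : 100 negatives): given candidate intervals, an ATAC-seq
signal track and the reference genome for a cell type, it predicts the
probability that each candidate folds in vivo in that cell type.

## Method

1. **Labeling.** A candidate is *active* (label 1) when its overlap with
   an in vivo peak `p` satisfies `overlap(c, p) >= f * |p|` with
   `f = 0.10` by default (the candidate-relative reading
   `f * |c|` is available via `label_config(fraction_of = "candidate")`).

2. **Features.** Each candidate's 2 kb center-anchored window yields a
   2,200-element vector

   `x = (a_1, ..., a_200, s_1, ..., s_2000)`

   where `a_i` is the mean ATAC signal in the i-th 10 bp bin and `s_j`
   encodes the j-th base ordinally (A,T,C,G → 0,1,2,3; other → 4), the
   sequence block being flagged as *unordered categorical*.

3. **Classifier.** A gradient-boosted decision tree ensemble (binary
   log-loss; 500 rounds, learning rate 0.1, 31 leaves, stochastic
   row/column subsampling 0.8) whose splits partition the sequence
   categories rather than thresholding their codes.

4. **Protocol.** Stratified half-split; the training half has its
   positives oversampled (duplicated) to parity with the negatives; the
   test half is never balanced. Metrics: accuracy, precision, recall and
   F1 at `score >= 0.5` (undefined ratios reported as `NaN`), AUROC
   (tie-aware rank form) and average precision as the step sum
   `AP = sum_n (R_n - R_{n-1}) P_n`. Experiments repeat over 5 seeds and
   report mean ± standard error. A cross-cell-line driver trains on one
   cell line's full (oversampled) dataset and tests on another's.

A self-contained synthetic-study generator (genome, planted G4-like
candidates, accessibility track with Gaussian bumps at active sites, in
vivo peaks) makes the entire pipeline testable without any downloads;
see the methods vignette (`vignettes/g4fold-methods.Rmd`) for its model
and every numerical convention.

## Worked example

A miniature study generated from a seed, labeled, featurized and pushed
through the one-cell-line protocol:

```r
library(g4fold)

cfg <- synthetic_config(n_chroms = 1, chrom_length = 1.2e6,
                        n_candidates = 400, active_fraction = 0.08)
study <- generate_synthetic_study(cfg, seed = 42, dir = tempfile())

candidates <- read_bed(study$candidates_bed)
peaks      <- read_bed(study$peaks_bed)
labeled    <- label_entries(candidates, peaks, label_config())
table(labeled$label)
#>   0   1
#> 379  21

genome <- read_genome(study$genome_fa)
atac   <- read_signal_track(study$atac_bedgraph)
fm     <- build_feature_matrix(labeled, atac, genome)
fm
#> feature_matrix: 400 x 2200 (mode=both, 2000 categorical columns)

ds <- labeled_dataset(fm, labeled$label, labeled$name)
one_cell_line_experiment(ds, gbdt_params(n_estimators = 150), seed = 7)
#> metrics @ 0.50: acc=0.9950 prec=1.0000 rec=0.9091 F1=0.9524 | AUROC=1.0000 AP=1.0000

repeated_evaluation(function(s)
  one_cell_line_experiment(ds, gbdt_params(n_estimators = 150), seed = s),
  base_seed = 7, k = 5)
#> repeated_report over 5 seeds (base 7 ):
#>   accuracy  0.9940 +/- 0.0019
#>   precision 1.0000 +/- 0.0000
#>   recall    0.8909 +/- 0.0340
#>   f1        0.9410 +/- 0.0188
#>   auroc     0.9998 +/- 0.0001
#>   ap        0.9970 +/- 0.0019
```

21 of 400 candidates are labeled active (they are exactly the planted
actives); trained on half the data, the model ranks the held-out actives
essentially perfectly (AUROC ~1) and, at the 0.5 threshold, recovers
~90% of them with no false positives — the planted accessibility signal
is strong by design.

The 200/2,000 column blocks can be ablated with
`one_cell_line_experiment(ds, mode = "atac")` / `mode = "seq"`; on this
study the sequence-only model collapses to chance-level AP, since active
and inactive candidates carry identically distributed motifs.

A thin command-line wrapper over the same functions is installed as
`exec/g4fold` (subcommands: label, extract-features, split, balance,
train, predict, evaluate, experiment, profile, simulate).

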