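suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# --- tiny fixture builders --------------------------------------------------

random_genome <- function(len, seed, chrom = "chr1") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  g <- DNAStringSet(s)
  names(g) <- chrom
  g
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 1000L, max_len = 60L) {
  set.seed(seed)
  s <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_len, n, replace = TRUE)
  GRanges(sample(chroms, n, replace = TRUE), IRanges(s, width = w))
}

track_from_blocks <- function(chrom, starts, ends, scores,
                              seqlen = max(ends) + 100L) {
  gr <- GRanges(chrom, IRanges(starts, ends), score = scores)
  sl <- stats::setNames(seqlen, chrom)
  signal_track(gr, seqlengths = sl)
}

constant_track <- function(chrom = "chr1", value = 1, len = 10000L) {
  track_from_blocks(chrom, 1L, len, value, seqlen = len)
}

# dataset with n_pos/n_neg rows and a single feature column
count_dataset <- function(n_pos, n_neg) {
  n <- n_pos + n_neg
  labeled_dataset(matrix(0, nrow = n, ncol = 1L),
                  c(rep(1L, n_pos), rep(0L, n_neg)))
}

# small dataset whose label is a simple function of one feature (+ noise cols)
separable_dataset <- function(n = 200L, seed = 1L, margin = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- ifelse(y == 1L, margin + runif(n), -margin - runif(n))
  x <- cbind(x1, matrix(rnorm(3L * n), ncol = 3L))
  colnames(x) <- paste0("f", 1:4)
  labeled_dataset(x, y)
}

# --- independent oracles ----------------------------------------------------

# per-base set-intersection overlap of two 1-based closed intervals
oracle_overlap <- function(chrom_a, s_a, e_a, chrom_b, s_b, e_b) {
  if (chrom_a != chrom_b) return(0L)
  length(intersect(seq(s_a, e_a), seq(s_b, e_b)))
}

# doubly nested-loop labeling on plain vectors (per-base set intersection)
oracle_labels <- function(cands, peaks, fraction, fraction_of,
                          aggregation = "per_peak") {
  ca <- as.character(seqnames(cands)); cs <- start(cands); ce <- end(cands)
  pa <- as.character(seqnames(peaks)); ps <- start(peaks); pe <- end(peaks)
  cw <- width(cands); pw <- width(peaks)
  vapply(seq_along(cs), function(i) {
    ov <- vapply(seq_along(ps), function(j) {
      oracle_overlap(ca[i], cs[i], ce[i], pa[j], ps[j], pe[j])
    }, integer(1))
    if (aggregation == "per_peak") {
      ref <- if (fraction_of == "peak") pw else rep(cw[i], length(ps))
      as.integer(any(ov >= fraction * ref))
    } else {
      as.integer(sum(ov) >= fraction * cw[i])
    }
  }, integer(1))
}

# brute-force metrics: pair-counting AUROC and explicit step-sum AP
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NaN)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_ap <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NaN)
  cuts <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0; ap <- 0
  for (t in cuts) {
    calls <- scores >= t
    tp <- sum(calls & labels == 1)
    recall <- tp / n_pos
    precision <- tp / sum(calls)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

small_synth_config <- function(n_chroms = 1L, chrom_length = 9e5,
                               n_candidates = 300L, active_fraction = 0.05,
                               ...) {
  synthetic_config(n_chroms = n_chroms, chrom_length = chrom_length,
                   n_candidates = n_candidates,
                   active_fraction = active_fraction, ...)
}
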