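# Active/inactive labeling of candidate G4 intervals by fractional overlap
# with in vivo G4 peaks (G4 ChIP-seq / CUT&Tag).

#' Labeling configuration
#'
#' A candidate is labeled active when its overlap with an in vivo peak
#' reaches `overlap_fraction` of a reference length. The reference is the
#' peak length (`fraction_of = "peak"`, the default) or the candidate's own
#' length (`fraction_of = "candidate"`). With `aggregation = "per_peak"`
#' a single sufficient peak makes a positive; with `"summed"` the total
#' overlap across all peaks is compared against the candidate-relative
#' threshold (a summed peak-relative threshold is ill-defined and
#' rejected).
#'
#' @param overlap_fraction Fraction in (0, 1]; default 0.10.
#' @param fraction_of `"peak"` or `"candidate"`.
#' @param aggregation `"per_peak"` or `"summed"`.
#' @return A `label_config` list.
#' @export
label_config <- function(overlap_fraction = 0.10,
                         fraction_of = c("peak", "candidate"),
                         aggregation = c("per_peak", "summed")) {
  fraction_of <- match.arg(fraction_of)
  aggregation <- match.arg(aggregation)
  if (!is.numeric(overlap_fraction) || length(overlap_fraction) != 1L ||
      overlap_fraction <= 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be a single number in (0, 1]")
  }
  if (aggregation == "summed" && fraction_of == "peak") {
    stop("aggregation = 'summed' requires fraction_of = 'candidate': ",
         "a summed overlap has no single reference peak")
  }
  structure(list(overlap_fraction = overlap_fraction,
                 fraction_of = fraction_of,
                 aggregation = aggregation),
            class = "label_config")
}

#' Overlap length between two intervals in base pairs
#'
#' Strand is ignored; intervals on different chromosomes overlap by 0.
#'
#' @param a,b Length-1 `GRanges`.
#' @return Integer overlap in bp (0 when disjoint).
#' @export
overlap_length <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(seqnames(a)) != as.character(seqnames(b))) return(0L)
  max(0L, min(end(a), end(b)) - max(start(a), start(b)) + 1L)
}

#' Label candidate intervals as active or inactive
#'
#' Each candidate receives exactly one binary label: 1 (active, supported
#' by in vivo peak overlap at the configured threshold) or 0 (inactive).
#' The threshold comparison is inclusive (overlap >= fraction x reference
#' length). Strand is ignored.
#'
#' @param candidates `GRanges` of candidate G4 intervals (e.g. G4-seq
#'   entries).
#' @param invivo `GRanges` of in vivo G4 peaks.
#' @param cfg A [label_config()].
#' @return `candidates` with an integer `label` metadata column.
#' @examples
#' cand <- GenomicRanges::GRanges("chr1:101-140")
#' peak <- GenomicRanges::GRanges("chr1:121-320")
#' label_entries(cand, peak, label_config())$label  # 1: overlap 20 >= 10% of 200
#' @export
label_entries <- function(candidates, invivo, cfg = label_config()) {
  stopifnot(inherits(cfg, "label_config"))
  labels <- integer(length(candidates))
  if (length(candidates) > 0L && length(invivo) > 0L) {
    hits <- findOverlaps(candidates, invivo, ignore.strand = TRUE)
    if (length(hits) > 0L) {
      ov <- GenomicRanges::width(pintersect(
        candidates[queryHits(hits)], invivo[subjectHits(hits)],
        ignore.strand = TRUE))
      ref_len <- switch(cfg$fraction_of,
        peak = GenomicRanges::width(invivo)[subjectHits(hits)],
        candidate = GenomicRanges::width(candidates)[queryHits(hits)])
      if (cfg$aggregation == "per_peak") {
        pos <- unique(queryHits(hits)[ov >= cfg$overlap_fraction * ref_len])
      } else {
        summed <- tapply(ov, queryHits(hits), sum)
        cand_idx <- as.integer(names(summed))
        thr <- cfg$overlap_fraction *
          GenomicRanges::width(candidates)[cand_idx]
        pos <- cand_idx[as.numeric(summed) >= thr]
      }
      labels[pos] <- 1L
    }
  }
  mcols(candidates)$label <- labels
  candidates
}
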