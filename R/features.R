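# Feature construction: a candidate interval becomes a 2,200-element vector
# (200 binned ATAC-seq window means + 2,000 ordinal-encoded bases) from a
# 2 kb window anchored at the candidate's center.

#' Feature-construction configuration
#'
#' @param flank Bases on each side of the candidate center (default 1000,
#'   i.e. a 2 kb window).
#' @param window ATAC bin width in bp (default 10); must divide `2 * flank`.
#' @param unknown_code Integer code for N/ambiguous bases (default 4).
#' @param strand_orient If `TRUE` (default), minus-strand candidates have
#'   their sequence reverse-complemented and their ATAC vector reversed so
#'   G-tract patterns read in a strand-consistent direction.
#' @return A `feature_config` list; `n_windows = 2 * flank / window` and
#'   `seq_len = 2 * flank` are precomputed.
#' @export
feature_config <- function(flank = 1000L, window = 10L,
                           unknown_code = 4L, strand_orient = TRUE) {
  flank <- as.integer(flank); window <- as.integer(window)
  if (flank <= 0L || window <= 0L || (2L * flank) %% window != 0L) {
    stop("window must divide 2 * flank")
  }
  structure(list(flank = flank, window = window,
                 base_codes = c(A = 0L, T = 1L, C = 2L, G = 3L),
                 unknown_code = as.integer(unknown_code),
                 strand_orient = isTRUE(strand_orient),
                 n_windows = 2L * flank %/% window,
                 seq_len = 2L * flank),
            class = "feature_config")
}

#' Extend an interval to a fixed-width window around its center
#'
#' The center of an interval of length L starting at `start` is
#' `start + floor(L / 2)` (0-based midpoint convention); the result spans
#' `flank` bases on each side of it and preserves strand.
#'
#' @param iv A `GRanges` (any length; vectorised).
#' @param cfg A [feature_config()].
#' @return A `GRanges` of identical length, every interval exactly
#'   `2 * flank` wide. Windows may extend beyond chromosome bounds;
#'   downstream fetches pad.
#' @export
extend_to_region <- function(iv, cfg = feature_config()) {
  # 0-based center start0 + floor(len/2); in 1-based GRanges coordinates the
  # window [center - flank, center + flank) becomes
  # [start + floor(len/2) - flank, ...] of width 2*flank
  center0 <- (start(iv) - 1L) + GenomicRanges::width(iv) %/% 2L
  out <- GRanges(seqnames(iv),
                 IRanges(start = center0 - cfg$flank + 1L,
                         width = 2L * cfg$flank),
                 strand = strand(iv))
  suppressWarnings(seqlengths(out) <- seqlengths(iv))
  out
}

#' Binned ATAC-seq feature for one window
#'
#' The window is divided into `n_windows` non-overlapping bins of `window`
#' bp and the per-base signal (zeros where unstored) is averaged within
#' each bin. Minus-strand windows are reversed when `cfg$strand_orient`.
#'
#' @param region A length-1 `GRanges` of width `2 * flank`.
#' @param track A `signal_track`.
#' @param cfg A [feature_config()].
#' @return Numeric vector of length `cfg$n_windows`.
#' @export
atac_feature <- function(region, track, cfg = feature_config()) {
  stopifnot(GenomicRanges::width(region) == cfg$seq_len)
  sig <- fetch_signal(track, region)
  v <- colMeans(matrix(sig, nrow = cfg$window))
  if (cfg$strand_orient && as.character(strand(region)) == "-") {
    v <- rev(v)
  }
  v
}

#' Ordinal-encoded sequence feature for one window
#'
#' Bases map A->0, T->1, C->2, G->3; anything else (N, ambiguity codes,
#' out-of-chromosome padding) maps to `cfg$unknown_code`. Minus-strand
#' windows are reverse-complemented before encoding when
#' `cfg$strand_orient`. The codes are unordered category identifiers, not
#' magnitudes; the classifier is told so via the feature schema.
#'
#' @param region A length-1 `GRanges` of width `2 * flank`.
#' @param genome A `DNAStringSet`.
#' @param cfg A [feature_config()].
#' @return Integer vector of length `2 * flank` with values in
#'   `{0, 1, 2, 3, unknown_code}`.
#' @export
sequence_feature <- function(region, genome, cfg = feature_config()) {
  stopifnot(GenomicRanges::width(region) == cfg$seq_len)
  s <- fetch_sequence(genome, region)
  if (cfg$strand_orient && as.character(strand(region)) == "-") {
    s <- as.character(reverseComplement(DNAStringSet(s))[[1L]])
  }
  encode_bases(s, cfg)
}

# vectorised base -> code mapping on a single string
encode_bases <- function(s, cfg) {
  codes <- cfg$base_codes[strsplit(s, "", fixed = TRUE)[[1L]]]
  codes[is.na(codes)] <- cfg$unknown_code
  unname(codes)
}

#' Build the feature matrix for labeled candidates
#'
#' One row per candidate (input order preserved). In `mode = "both"` the
#' first `n_windows` columns are ATAC bin means and the last `2 * flank`
#' columns are sequence codes flagged categorical; `"atac"` and `"seq"`
#' select a single block (for feature-ablation experiments).
#'
#' @param candidates `GRanges` of candidates (typically with a `label`
#'   column from [label_entries()]).
#' @param track A `signal_track` (may be `NULL` in `mode = "seq"`).
#' @param genome A `DNAStringSet` (may be `NULL` in `mode = "atac"`).
#' @param cfg A [feature_config()].
#' @param mode `"both"`, `"atac"` or `"seq"`.
#' @return A `feature_matrix`: list with `x` (numeric matrix),
#'   `categorical` (logical column flags), `mode`, and the `config`.
#' @export
build_feature_matrix <- function(candidates, track = NULL, genome = NULL,
                                 cfg = feature_config(),
                                 mode = c("both", "atac", "seq")) {
  mode <- match.arg(mode)
  n <- length(candidates)
  chroms <- unique(as.character(seqnames(candidates)))
  if (mode != "seq") {
    stopifnot(inherits(track, "signal_track"))
    missing_tr <- setdiff(chroms, names(track$seqlengths))
    if (length(missing_tr)) {
      stop("candidate chromosomes absent from signal track: ",
           paste(missing_tr, collapse = ", "))
    }
  }
  if (mode != "atac") {
    stopifnot(inherits(genome, "DNAStringSet"))
    missing_g <- setdiff(chroms, names(genome))
    if (length(missing_g)) {
      stop("candidate chromosomes absent from genome: ",
           paste(missing_g, collapse = ", "))
    }
  }
  regions <- extend_to_region(candidates, cfg)
  atac <- if (mode != "seq") atac_block(regions, track, cfg)
  seqm <- if (mode != "atac") sequence_block(regions, genome, cfg)
  x <- switch(mode,
    both = cbind(atac, seqm),
    atac = atac,
    seq  = seqm)
  if (n == 0L) {
    ncols <- switch(mode, both = cfg$n_windows + cfg$seq_len,
                    atac = cfg$n_windows, seq = cfg$seq_len)
    x <- matrix(numeric(0), nrow = 0L, ncol = ncols)
  }
  colnames(x) <- switch(mode,
    both = c(paste0("atac", seq_len(cfg$n_windows)),
             paste0("seq", seq_len(cfg$seq_len))),
    atac = paste0("atac", seq_len(cfg$n_windows)),
    seq  = paste0("seq", seq_len(cfg$seq_len)))
  categorical <- switch(mode,
    both = c(rep(FALSE, cfg$n_windows), rep(TRUE, cfg$seq_len)),
    atac = rep(FALSE, cfg$n_windows),
    seq  = rep(TRUE, cfg$seq_len))
  structure(list(x = x, categorical = categorical, mode = mode,
                 config = cfg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "x", ncol(x$x),
      sprintf("(mode=%s, %d categorical columns)\n",
              x$mode, sum(x$categorical)))
  invisible(x)
}

# ---- vectorized whole-matrix paths ----------------------------------------
# Same arithmetic as atac_feature()/sequence_feature() applied row by row,
# but grouped by chromosome with plain-integer indexing so the per-row S4
# overhead disappears. The composition tests pin the two paths together.

atac_block <- function(regions, track, cfg) {
  n <- length(regions)
  out <- matrix(0, nrow = n, ncol = cfg$n_windows)
  ch_all <- as.character(seqnames(regions))
  s_all <- start(regions); e_all <- end(regions)
  minus <- cfg$strand_orient & as.character(strand(regions)) == "-"
  for (ch in unique(ch_all)) {
    rows <- which(ch_all == ch)
    rle <- if (ch %in% names(track$cov)) track$cov[[ch]]
    stored_len <- if (is.null(rle)) 0L else length(rle)
    for (i in rows) {
      s <- s_all[i]; e <- e_all[i]
      sig <- numeric(e - s + 1L)
      s_in <- max(1L, s); e_in <- min(stored_len, e)
      if (s_in <= e_in) {
        sig[(s_in - s + 1L):(e_in - s + 1L)] <- as.numeric(rle[s_in:e_in])
      }
      v <- colMeans(matrix(sig, nrow = cfg$window))
      out[i, ] <- if (minus[i]) rev(v) else v
    }
  }
  out
}

sequence_block <- function(regions, genome, cfg) {
  n <- length(regions)
  out <- matrix(cfg$unknown_code, nrow = n, ncol = cfg$seq_len)
  # ASCII lookup: A/T/C/G (and lowercase) -> codes, all else -> unknown
  lut <- rep.int(cfg$unknown_code, 127L)
  for (b in names(cfg$base_codes)) {
    lut[utf8ToInt(b)] <- cfg$base_codes[[b]]
    lut[utf8ToInt(tolower(b))] <- cfg$base_codes[[b]]
  }
  ch_all <- as.character(seqnames(regions))
  s_all <- start(regions); e_all <- end(regions)
  minus <- cfg$strand_orient & as.character(strand(regions)) == "-"
  for (ch in unique(ch_all)) {
    rows <- which(ch_all == ch)
    chrom_len <- length(genome[[ch]])
    s <- s_all[rows]; e <- e_all[rows]
    left_pad <- pmax(0L, 1L - s)
    right_pad <- pmax(0L, e - chrom_len)
    n_padded <- sum(left_pad > 0L | right_pad > 0L)
    if (n_padded > 0L) {
      warning(n_padded, " window(s) on ", ch,
              " extend beyond the chromosome; padding with N")
    }
    s_in <- pmin(pmax(1L, s), chrom_len + 1L)
    e_in <- pmax(pmin(chrom_len, e), s_in - 1L)   # width >= 0 when fully out
    win <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges(s_in, e_in)))
    win <- paste0(strrep("N", left_pad), win, strrep("N", right_pad))
    if (any(minus[rows])) {
      m <- minus[rows]
      win[m] <- as.character(reverseComplement(DNAStringSet(win[m])))
    }
    codes <- lut[utf8ToInt(paste0(win, collapse = ""))]
    out[rows, ] <- matrix(codes, ncol = cfg$seq_len, byrow = TRUE)
  }
  out
}

#' Profile a signal track around a set of sites
#'
#' Bins each site's center-anchored window exactly like [atac_feature()]
#' (strand-aware reversal included). `aggregate = "mean"` returns the
#' across-site average profile (line-chart substrate); `"per_site_matrix"`
#' returns one row per site (heatmap substrate, row means give a boxplot
#' substrate).
#'
#' @param sites `GRanges` of sites (must be non-empty).
#' @param track A `signal_track`.
#' @param flank Half-window in bp (default 1000).
#' @param binsize Bin width in bp (default 10); must divide `2 * flank`.
#' @param aggregate `"mean"` or `"per_site_matrix"`.
#' @return Numeric vector (`mean`) or matrix (`per_site_matrix`) with
#'   `2 * flank / binsize` columns.
#' @export
signal_profile <- function(sites, track, flank = 1000L, binsize = 10L,
                           aggregate = c("mean", "per_site_matrix")) {
  aggregate <- match.arg(aggregate)
  if (length(sites) == 0L) stop("signal_profile needs at least one site")
  cfg <- feature_config(flank = flank, window = binsize)
  regions <- extend_to_region(sites, cfg)
  m <- t(vapply(seq_along(sites),
                function(i) atac_feature(regions[i], track, cfg),
                numeric(cfg$n_windows)))
  if (aggregate == "mean") colMeans(m) else m
}
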