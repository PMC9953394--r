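#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   findOverlaps pintersect coverage resize shift sort
#' @importFrom IRanges IRanges Views viewMeans ranges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<-
#'   seqinfo Seqinfo
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet reverseComplement subseq subseq<- width
NULL

# Coordinate convention: intervals are GRanges (1-based, closed) inside the
# package; BED files are 0-based half-open at the file boundary. read_bed()
# and write_bed() perform the +1/-0 conversion, so a read/write round trip
# is the identity on BED coordinates.

#' Read a BED file into a sorted GRanges
#'
#' Reads BED3/BED6 (tab- or whitespace-separated, 0-based half-open).
#' `track`, `browser` and `#` comment lines are skipped. Strand is taken
#' from column 6 when present, otherwise `*`; column 4 becomes `name` and
#' column 5 `score`. Output is sorted by (chromosome, start).
#'
#' @param path Path to a BED file.
#' @param min_columns Minimum number of columns each data line must have
#'   (default 3).
#' @return A `GRanges`, sorted, with `name`/`score` metadata columns when
#'   the input has more than 3 columns.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t140\tg4_1\t0\t+", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path, min_columns = 3L) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GRanges())
  }
  fields <- strsplit(lines[idx], "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < min_columns)) {
    bad <- idx[which(nf < min_columns)[1L]]
    stop("BED parse error at line ", bad, ": expected >= ", min_columns,
         " columns, got ", nf[which(nf < min_columns)[1L]])
  }
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0))
  if (length(bad)) {
    stop("BED parse error at line ", idx[bad[1L]],
         ": non-integer coordinates")
  }
  bad <- which(s0 >= e0 | s0 < 0)
  if (length(bad)) {
    stop("BED parse error at line ", idx[bad[1L]],
         ": invalid interval (start >= end or negative start)")
  }
  str <- if (all(nf >= 6L)) {
    st <- vapply(fields, `[`, "", 6L)
    ifelse(st %in% c("+", "-"), st, "*")
  } else "*"
  gr <- GRanges(chrom, IRanges(start = s0 + 1L, end = e0), strand = str)
  seqlevels(gr) <- sort(seqlevels(gr))   # sort by chromosome name, not appearance
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 5L)) {
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[`, "", 5L)))
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges to a BED file
#'
#' Emits BED6 when `name` or `score` metadata are present (missing ones
#' filled with `.`/`0`), else BED3. Coordinates are converted back to
#' 0-based half-open.
#'
#' @param gr A `GRanges`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  n <- length(gr)
  chrom <- as.character(seqnames(gr))
  s0 <- format(start(gr) - 1L, scientific = FALSE, trim = TRUE)
  e0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  has_meta <- any(c("name", "score") %in% names(mcols(gr))) ||
    any(as.character(strand(gr)) != "*")
  if (has_meta && n > 0L) {
    nm <- if ("name" %in% names(mcols(gr))) mcols(gr)$name else rep(".", n)
    sc <- if ("score" %in% names(mcols(gr))) mcols(gr)$score else rep(0, n)
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    out <- paste(chrom, s0, e0, nm, sc, st, sep = "\t")
  } else {
    out <- paste(chrom, s0, e0, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Load a reference genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A `DNAStringSet`, names truncated at the first whitespace.
#' @export
read_genome <- function(path) {
  genome <- readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Fetch the sequence under an interval, padding beyond chromosome ends
#'
#' Positions outside `[1, chrom_length]` are returned as `N` so that
#' fixed-width windows near chromosome edges keep their length. Soft-masked
#' (lowercase) bases are uppercased.
#'
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @param iv A length-1 `GRanges`.
#' @return A character scalar of exactly `width(iv)` bases.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' fetch_sequence(genome, GenomicRanges::GRanges("chr1:3-6"))  # "GTAC"
#' @export
fetch_sequence <- function(genome, iv) {
  stopifnot(length(iv) == 1L)
  chrom <- as.character(seqnames(iv))
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom)
  }
  chrom_len <- length(genome[[chrom]])
  s <- start(iv); e <- end(iv)
  left_pad <- max(0L, 1L - s)
  right_pad <- max(0L, e - chrom_len)
  if (left_pad > 0L || right_pad > 0L) {
    warning("interval ", chrom, ":", s, "-", e,
            " extends beyond chromosome; padding with N")
  }
  s_in <- max(1L, s); e_in <- min(chrom_len, e)
  core <- if (s_in <= e_in) {
    as.character(subseq(genome[[chrom]], s_in, e_in))
  } else ""
  toupper(paste0(strrep("N", left_pad), core, strrep("N", right_pad)))
}

# ---- SignalTrack -----------------------------------------------------------

#' Construct a signal track from a scored GRanges
#'
#' A `signal_track` is a per-base float coverage source: positions not
#' covered by any scored interval (or beyond the recorded chromosome
#' length) read as 0.
#'
#' @param gr A `GRanges` with a numeric `score` column (e.g. imported
#'   bedGraph/bigWig blocks).
#' @param seqlengths Optional named integer vector of chromosome lengths;
#'   defaults to lengths inferred from `gr`.
#' @return An object of class `signal_track` wrapping an `RleList`.
#' @export
signal_track <- function(gr, seqlengths = NULL) {
  if (length(gr) > 0 && !"score" %in% names(mcols(gr))) {
    stop("signal GRanges needs a 'score' column")
  }
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (any(is.na(sl))) {
      inferred <- tapply(end(gr), as.character(seqnames(gr)), max)
      sl[is.na(sl)] <- inferred[names(sl)[is.na(sl)]]
    }
    seqlengths <- sl
  }
  cov <- if (length(gr) > 0) {
    GenomicRanges::coverage(gr, weight = "score")
  } else {
    as(S4Vectors::Rle(numeric(0)), "RleList")[0]
  }
  structure(list(cov = cov, seqlengths = seqlengths),
            class = "signal_track")
}

#' Read a signal track from bigWig or bedGraph
#'
#' Format is sniffed from the file extension (`.bw`/`.bigwig` vs
#' `.bedgraph`/`.bg`/`.bdg`) and can be forced with `format`.
#'
#' @param path Path to the track file.
#' @param format `"auto"`, `"bigwig"` or `"bedgraph"`.
#' @return A `signal_track`.
#' @export
read_signal_track <- function(path, format = c("auto", "bigwig", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("bw", "bigwig")) "bigwig" else "bedgraph"
  }
  gr <- if (format == "bigwig") {
    rtracklayer::import(path, format = "BigWig")
  } else {
    rtracklayer::import(path, format = "bedGraph")
  }
  signal_track(gr)
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track with", length(x$cov), "chromosome(s)\n")
  for (ch in names(x$cov)) {
    cat(" ", ch, " length=", x$seqlengths[[ch]], "\n", sep = "")
  }
  invisible(x)
}

#' Fetch per-base signal under an interval
#'
#' Unstored and out-of-bounds positions read as 0, so the result always has
#' exactly `width(iv)` elements.
#'
#' @param track A `signal_track`.
#' @param iv A length-1 `GRanges`.
#' @return Numeric vector of length `width(iv)`.
#' @export
fetch_signal <- function(track, iv) {
  stopifnot(inherits(track, "signal_track"), length(iv) == 1L)
  chrom <- as.character(seqnames(iv))
  if (!chrom %in% names(track$seqlengths)) {
    stop("chromosome not in signal track: ", chrom)
  }
  s <- start(iv); e <- end(iv)
  n <- e - s + 1L
  out <- numeric(n)
  if (!chrom %in% names(track$cov)) return(out)
  rle <- track$cov[[chrom]]
  stored_len <- length(rle)
  s_in <- max(1L, s); e_in <- min(stored_len, e)
  if (s_in <= e_in) {
    out[(s_in - s + 1L):(e_in - s + 1L)] <-
      as.numeric(rle[s_in:e_in])
  }
  out
}
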