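test_that("read_bed maps fields, skips headers, and sorts", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test",
               "# comment",
               "chr2\t5\t30\tb\t0\t-",
               "chr1\t100\t140\tg4_1\t0\t+",
               "chr1\t10\t40\ta\t0\t+"), bed)
  gr <- read_bed(bed)
  expect_equal(length(gr), 3L)
  # sorted by (chrom, start); 0-based half-open -> 1-based closed
  expect_equal(as.character(seqnames(gr)), c("chr1", "chr1", "chr2"))
  expect_equal(start(gr), c(11L, 101L, 6L))
  expect_equal(end(gr), c(40L, 140L, 30L))
  expect_equal(as.character(strand(gr)), c("+", "+", "-"))
  expect_equal(gr$name, c("a", "g4_1", "b"))
})

test_that("read_bed sorts shuffled input like a naive sort", {
  set.seed(42)
  n <- 30L
  chrom <- sample(c("chr1", "chr10", "chr2"), n, replace = TRUE)
  s0 <- sample.int(5000L, n)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(chrom, s0, s0 + 25L, sep = "\t"), bed)
  gr <- read_bed(bed)
  ord <- order(chrom, s0)   # naive sort oracle
  expect_equal(as.character(seqnames(gr)), chrom[ord])
  expect_equal(start(gr) - 1L, s0[ord])
})

test_that("read_bed rejects malformed lines with the line number", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t40", "chr2\t50\t50"), bed)
  expect_error(read_bed(bed), "line 2")
  writeLines(c("chr1\tten\t40"), bed)
  expect_error(read_bed(bed), "line 1.*non-integer")
  writeLines("chr1\t10", bed)
  expect_error(read_bed(bed, min_columns = 3L), "line 1")
})

test_that("write_bed / read_bed round trip preserves coords, names, strand", {
  gr <- GRanges(c("chr1", "chr2", "chr1"),
                IRanges(c(11, 6, 101), c(40, 30, 140)),
                strand = c("+", "-", "*"),
                name = c("a", "b", "c"), score = c(1, 2, 3))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, bed)
  back <- read_bed(bed)
  srt <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  expect_equal(start(back), start(srt))
  expect_equal(end(back), end(srt))
  expect_equal(back$name, srt$name)
  # "*" strand is written as "." and read back as "*"
  expect_equal(as.character(strand(back)), as.character(strand(srt)))
  expect_equal(back$score, srt$score)
})

test_that("fetch_sequence slices, pads with N beyond bounds, uppercases", {
  genome <- DNAStringSet(c(chr1 = "ACGTACGT"))
  expect_equal(fetch_sequence(genome, GRanges("chr1:3-6")), "GTAC")
  # window starting before position 1 pads on the left
  expect_warning(
    left <- fetch_sequence(genome, GRanges("chr1", IRanges(-1, 2))),
    "padding")
  expect_equal(left, "NNAC")
  expect_warning(
    right <- fetch_sequence(genome, GRanges("chr1:7-10")), "padding")
  expect_equal(right, "GTNN")
  expect_error(fetch_sequence(genome, GRanges("chrX:1-4")), "chrX")
})

test_that("fetch_sequence matches a character-level slicing oracle", {
  genome <- random_genome(1000L, seed = 7)
  chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  set.seed(8)
  for (i in 1:50) {
    s <- sample.int(950L, 1L); w <- sample.int(50L, 1L)
    iv <- GRanges("chr1", IRanges(s, width = w))
    expect_identical(fetch_sequence(genome, iv),
                     paste(chars[s:(s + w - 1L)], collapse = ""))
  }
})

test_that("fetch_signal obeys the zero-fill rule and exact lengths", {
  tr <- track_from_blocks("chr1", 11L, 20L, 3, seqlen = 100L)
  # value 3 on [11,20], query [16,25]
  expect_equal(fetch_signal(tr, GRanges("chr1:16-25")),
               c(3, 3, 3, 3, 3, 0, 0, 0, 0, 0))
  empty <- signal_track(GRanges(score = numeric(0)),
                        seqlengths = c(chr1 = 100L))
  expect_equal(fetch_signal(empty, GRanges("chr1:1-7")), rep(0, 7))
  # beyond the chromosome end still returns width(iv) elements
  expect_equal(length(fetch_signal(tr, GRanges("chr1:95-120"))), 26L)
  expect_error(fetch_signal(tr, GRanges("chrZ:1-5")), "chrZ")
})

test_that("fetch_signal equals a per-position dictionary lookup oracle", {
  starts <- c(10L, 60L, 200L); ends <- c(39L, 99L, 240L)
  scores <- c(1.5, -2, 0.25)
  tr <- track_from_blocks("chr1", starts, ends, scores, seqlen = 400L)
  dict <- numeric(400L)
  for (b in 1:3) dict[starts[b]:ends[b]] <- scores[b]
  set.seed(9)
  for (i in 1:20) {
    s <- sample.int(380L, 1L); w <- sample.int(80L, 1L)
    iv <- GRanges("chr1", IRanges(s, width = w))
    got <- fetch_signal(tr, iv)
    want <- vapply(s:(s + w - 1L),
                   function(p) if (p <= 400L) dict[p] else 0, numeric(1))
    expect_equal(got, want)
  }
})

test_that("bedGraph and bigWig backends agree through read_signal_track", {
  sl <- c(chr1 = 500L)
  gr <- GRanges("chr1", IRanges(c(1, 101, 301), c(100, 200, 400)),
                score = c(1.25, 0.5, 3), seqlengths = sl)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  bw <- withr::local_tempfile(fileext = ".bw")
  rtracklayer::export(gr, bg, format = "bedGraph")
  rtracklayer::export(gr, bw, format = "BigWig")
  iv <- GRanges("chr1:90-320")
  expect_equal(fetch_signal(read_signal_track(bg), iv),
               fetch_signal(read_signal_track(bw), iv))
})

test_that("0-based half-open to 1-based closed conversion is an involution", {
  iv <- random_intervals(25L, seed = 3)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(GenomicRanges::sort(iv, ignore.strand = TRUE), bed)
  back <- read_bed(bed)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(back, bed2)
  expect_identical(readLines(bed), readLines(bed2))
})
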