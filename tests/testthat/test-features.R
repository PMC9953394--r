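test_that("extend_to_region centers at the floor midpoint", {
  # BED candidate [1000,1030): center0 = 1015, window [15,2015)
  iv <- GRanges("chr1", IRanges(1001, 1030))
  reg <- extend_to_region(iv, feature_config())
  expect_equal(start(reg), 16L)   # 1-based for 0-based position 15
  expect_equal(end(reg), 2015L)
  expect_equal(width(reg), 2000L)
  # an interval already 2000 wide centered on its midpoint is a fixed point
  iv2 <- GRanges("chr2", IRanges(5001, 7000), strand = "-")
  reg2 <- extend_to_region(iv2, feature_config())
  expect_equal(start(reg2), 5001L)
  expect_equal(end(reg2), 7000L)
  expect_equal(as.character(strand(reg2)), "-")
  # width invariant on random inputs
  ivr <- random_intervals(100L, seed = 21, max_pos = 10000L)
  expect_true(all(width(extend_to_region(ivr, feature_config())) == 2000L))
})

test_that("atac_feature bins per-base means, constant and empty cases", {
  cfg <- feature_config()
  tr <- constant_track(value = 2, len = 20000L)
  reg <- GRanges("chr1", IRanges(3001, 5000))
  expect_equal(atac_feature(reg, tr, cfg), rep(2, 200))
  empty <- signal_track(GRanges(score = numeric(0)),
                        seqlengths = c(chr1 = 20000L))
  expect_equal(atac_feature(reg, empty, cfg), rep(0, 200))
})

test_that("atac_feature matches a brute-force windowed mean and is linear", {
  set.seed(22)
  starts <- seq(1L, 29901L, by = 100L)
  vals <- rnorm(length(starts))
  tr <- track_from_blocks("chr1", starts, starts + 99L, vals, seqlen = 30000L)
  tr3 <- track_from_blocks("chr1", starts, starts + 99L, 3 * vals,
                           seqlen = 30000L)
  cfg <- feature_config()
  for (i in 1:20) {
    s <- sample.int(27000L, 1L)
    reg <- GRanges("chr1", IRanges(s, width = 2000L))
    per_base <- fetch_signal(tr, reg)
    want <- vapply(seq_len(200L), function(w) {
      mean(per_base[((w - 1L) * 10L + 1L):(w * 10L)])
    }, numeric(1))
    got <- atac_feature(reg, tr, cfg)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(atac_feature(reg, tr3, cfg), 3 * got, tolerance = 1e-9)
  }
})

test_that("atac_feature reverses minus-strand windows when oriented", {
  tr <- track_from_blocks("chr1", 1L, 1000L, 5, seqlen = 20000L)
  cfg <- feature_config()
  plus <- atac_feature(GRanges("chr1", IRanges(501, 2500), strand = "+"),
                       tr, cfg)
  minus <- atac_feature(GRanges("chr1", IRanges(501, 2500), strand = "-"),
                        tr, cfg)
  expect_equal(minus, rev(plus))
  cfg_off <- feature_config(strand_orient = FALSE)
  expect_equal(atac_feature(GRanges("chr1", IRanges(501, 2500), strand = "-"),
                            tr, cfg_off), plus)
})

test_that("sequence_feature encodes A/T/C/G ordinally and N as unknown", {
  cfg <- feature_config(flank = 2L, window = 1L)
  genome <- DNAStringSet(c(chr1 = "ATCGNNNN"))
  expect_equal(sequence_feature(GRanges("chr1:1-4"), genome, cfg),
               c(0L, 1L, 2L, 3L))
  expect_equal(sequence_feature(GRanges("chr1:5-8"), genome, cfg),
               rep(4L, 4))
  # minus strand is reverse-complemented first: ATCG -> CGAT -> 2,3,0,1
  expect_equal(sequence_feature(GRanges("chr1:1-4:-"), genome, cfg),
               c(2L, 3L, 0L, 1L))
  # orientation applied twice is an involution on the codes
  twice <- sequence_feature(GRanges("chr1:1-4:-"), genome, cfg)
  genome_rc <- DNAStringSet(c(chr1 = "CGAT"))
  expect_equal(sequence_feature(GRanges("chr1:1-4:-"), genome_rc, cfg),
               sequence_feature(GRanges("chr1:1-4:+"), genome, cfg))
  expect_length(twice, 4L)
})

test_that("build_feature_matrix has the contracted shape and flags", {
  genome <- random_genome(30000L, seed = 23)
  tr <- constant_track(len = 30000L)
  cands <- GRanges("chr1", IRanges(c(5001, 9001, 15001), width = 30))
  fm <- build_feature_matrix(cands, tr, genome)
  expect_equal(dim(fm$x), c(3L, 2200L))
  expect_equal(sum(fm$categorical), 2000L)
  expect_true(all(fm$categorical[201:2200]))
  expect_false(any(fm$categorical[1:200]))
  fm_atac <- build_feature_matrix(cands, tr, NULL, mode = "atac")
  expect_equal(dim(fm_atac$x), c(3L, 200L))
  expect_false(any(fm_atac$categorical))
  fm_seq <- build_feature_matrix(cands, NULL, genome, mode = "seq")
  expect_equal(dim(fm_seq$x), c(3L, 2000L))
  expect_true(all(fm_seq$categorical))
})

test_that("feature matrix rows equal the single-entry operations", {
  genome <- random_genome(30000L, seed = 24)
  set.seed(25)
  starts <- seq(1L, 29901L, by = 100L)
  tr <- track_from_blocks("chr1", starts, starts + 99L,
                          rnorm(length(starts)), seqlen = 30000L)
  cfg <- feature_config()
  cands <- GRanges("chr1", IRanges(c(4001, 12000, 22345), width = 25),
                   strand = c("+", "-", "+"))
  fm <- build_feature_matrix(cands, tr, genome, cfg)
  regions <- extend_to_region(cands, cfg)
  for (i in 1:3) {
    expect_equal(unname(fm$x[i, 1:200]),
                 atac_feature(regions[i], tr, cfg))
    expect_equal(unname(fm$x[i, 201:2200]),
                 as.numeric(sequence_feature(regions[i], genome, cfg)))
  }
})

test_that("chromosome naming mismatches are reported explicitly", {
  genome <- random_genome(30000L, seed = 26)
  tr <- constant_track(len = 30000L)
  cands <- GRanges("1", IRanges(5001, 5030))   # Ensembl-style name
  expect_error(build_feature_matrix(cands, tr, genome), "1")
})

test_that("signal_profile aggregates center-anchored windows", {
  tr <- constant_track(value = 1, len = 20000L)
  site <- GRanges("chr1", IRanges(5001, 5030))
  expect_equal(signal_profile(site, tr), rep(1, 200))
  # two mirrored ramp signals average to a symmetric (flat) profile:
  # bin means 1..200 at site 1 and 200..1 at site 2 -> mean 100.5 throughout
  up <- GRanges("chr1", IRanges(seq(4001L, 5991L, 10L), width = 10L),
                score = 1:200)
  down <- GRanges("chr1", IRanges(seq(14001L, 15991L, 10L), width = 10L),
                  score = 200:1)
  tri <- signal_track(c(up, down), seqlengths = c(chr1 = 20000L))
  sites <- GRanges("chr1", IRanges(c(4991, 14991), width = 20))
  prof <- signal_profile(sites, tri)
  expect_equal(prof, rev(prof))
  expect_equal(prof, rep(100.5, 200))
  m <- signal_profile(sites, tri, aggregate = "per_site_matrix")
  expect_equal(dim(m), c(2L, 200L))
  expect_equal(colMeans(m), prof)
  expect_error(signal_profile(GRanges(), tr), "at least one site")
})
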