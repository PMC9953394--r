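# Self-contained synthetic study generator: a miniature genome with planted
# G4-like candidate motifs, an accessibility track whose peaks mark the
# designated active candidates, and in vivo peak calls centered on them.
# The planted signal travels through accessibility only (active and
# inactive candidates carry identical motif structure), so a classifier
# can recover activity from the ATAC block but not from sequence alone.
# Truth labels live in a separate table that no pipeline step reads.

#' Synthetic study configuration
#'
#' Defaults emulate the shape of whole-genome candidate sets: ~1% of
#' candidates active (mirroring the ~4e3 / 4.3e5 skew of real cell lines,
#' at desk scale), G4-like motifs of four G3-runs with 1-7 bp loops,
#' accessibility bumps of a few hundred bp over low background noise, and
#' ~100 bp in vivo peaks (the low end of ChIP-grade peak resolution).
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 2.6e6).
#' @param n_candidates Total candidates planted (default 2000).
#' @param active_fraction Bernoulli probability a candidate is active
#'   (default 0.01).
#' @param atac_peak_height Peak height of the Gaussian accessibility bump
#'   added at each active candidate (default 4; 0 gives a null study).
#' @param atac_peak_sd Bump standard deviation in bp (default 150).
#' @param background_noise_sd SD of the half-normal background noise
#'   (default 0.25), laid down in blocks of `background_block` bp.
#' @param background_block Background block width in bp (default 50).
#' @param invivo_peak_halfwidth Half-width of in vivo peaks in bp
#'   (default 50, i.e. ~100 bp peaks).
#' @param peak_jitter Maximum random shift of peak centers in bp
#'   (default 0: peaks exactly centered, making label recovery exact).
#' @param motif_g_run Length of each G-run (default 3).
#' @param motif_n_runs Number of G-runs (default 4).
#' @param motif_loop_range Loop length range between G-runs (default 1:7,
#'   loops drawn from {A, C, T}).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_chroms = 2L, chrom_length = 2.6e6,
                             n_candidates = 2000L, active_fraction = 0.01,
                             atac_peak_height = 4, atac_peak_sd = 150,
                             background_noise_sd = 0.25,
                             background_block = 50L,
                             invivo_peak_halfwidth = 50L,
                             peak_jitter = 0L,
                             motif_g_run = 3L, motif_n_runs = 4L,
                             motif_loop_range = 1:7) {
  stopifnot(active_fraction > 0, active_fraction < 1,
            chrom_length > 0, n_candidates > 0, atac_peak_height >= 0)
  structure(list(n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 n_candidates = as.integer(n_candidates),
                 active_fraction = active_fraction,
                 atac_peak_height = atac_peak_height,
                 atac_peak_sd = atac_peak_sd,
                 background_noise_sd = background_noise_sd,
                 background_block = as.integer(background_block),
                 invivo_peak_halfwidth = as.integer(invivo_peak_halfwidth),
                 peak_jitter = as.integer(peak_jitter),
                 motif_g_run = as.integer(motif_g_run),
                 motif_n_runs = as.integer(motif_n_runs),
                 motif_loop_range = as.integer(motif_loop_range)),
            class = "synthetic_config")
}

synthetic_seqlengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                  paste0("chr", seq_len(cfg$n_chroms)))
}

#' Generate a random background genome
#'
#' I.i.d. uniform A/C/G/T, N-free, deterministic under `seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A `DNAStringSet` with `n_chroms` chromosomes.
#' @export
generate_genome <- function(cfg = synthetic_config(), seed = 1L) {
  rng <- local_rng(seed)
  base_ints <- utf8ToInt("ACGT")
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    idx <- with_rng(rng, sample.int(4L, cfg$chrom_length, replace = TRUE))
    intToUtf8(base_ints[idx])
  }, character(1))
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  genome
}

#' Plant candidate G4 motifs and designate the active subset
#'
#' Writes `n_candidates` G4-like motifs (G-runs separated by random A/C/T
#' loops) at evenly spaced, non-overlapping loci, spaced widely enough
#' that 2 kb feature windows of neighbouring candidates never share an
#' accessibility bump. Activity is drawn Bernoulli(`active_fraction`) per
#' candidate; active and inactive candidates have identically distributed
#' motifs.
#'
#' @param genome A `DNAStringSet` from [generate_genome()].
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return List: `genome` (with motifs written in), `candidates` (sorted
#'   `GRanges` with `name`), and `truth` (data frame `id`, `active` — keep
#'   it away from pipeline inputs).
#' @export
plant_candidates <- function(genome, cfg = synthetic_config(), seed = 1L) {
  rng <- local_rng(seed)
  sl <- synthetic_seqlengths(cfg)
  per_chrom <- diff(round(seq(0, cfg$n_candidates,
                              length.out = cfg$n_chroms + 1L)))
  margin <- 2000L
  max_motif <- cfg$motif_n_runs * cfg$motif_g_run +
    (cfg$motif_n_runs - 1L) * max(cfg$motif_loop_range)
  min_spacing <- 2L * margin + max_motif
  chroms <- character(0); starts <- integer(0); widths <- integer(0)
  for (ci in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ci]
    if (k == 0L) next
    avail <- cfg$chrom_length - 2L * margin
    spacing <- if (k > 1L) (avail - max_motif) %/% (k - 1L) else 0L
    if (avail < max_motif || (k > 1L && spacing < min_spacing / 2L)) {
      stop("insufficient genome space for ", k, " candidates on a ",
           cfg$chrom_length, " bp chromosome")
    }
    centers <- margin + 1L + spacing * (seq_len(k) - 1L)
    loops_n <- cfg$motif_n_runs - 1L
    g_run <- strrep("G", cfg$motif_g_run)
    motifs <- vapply(seq_len(k), function(j) {
      loop_lens <- with_rng(rng, sample(cfg$motif_loop_range, loops_n,
                                        replace = TRUE))
      loops <- vapply(loop_lens, function(L) {
        paste(c("A", "C", "T")[with_rng(rng, sample.int(3L, L, TRUE))],
              collapse = "")
      }, character(1))
      paste0(paste0(g_run, c(loops, "")), collapse = "")
    }, character(1))
    w <- nchar(motifs)
    # equal-width in-place replacement: no coordinate shift
    genome[[ci]] <- Biostrings::replaceAt(
      genome[[ci]], IRanges(centers, width = w), motifs)
    chroms <- c(chroms, rep(names(genome)[ci], k))
    starts <- c(starts, centers); widths <- c(widths, w)
  }
  cand <- GRanges(chroms, IRanges(start = starts, width = widths),
                  strand = "*", seqlengths = sl)
  mcols(cand)$name <- sprintf("g4_%04d", seq_along(cand))
  active <- with_rng(rng,
    stats::rbinom(length(cand), 1L, cfg$active_fraction))
  list(genome = genome, candidates = cand,
       truth = data.frame(id = mcols(cand)$name, active = as.integer(active)))
}

#' Generate the accessibility track with bumps at active candidates
#'
#' Background is half-normal noise (`|N(0, background_noise_sd)|`) in
#' fixed-width blocks; each active candidate adds a Gaussian bump of
#' height `atac_peak_height` and SD `atac_peak_sd` centered on it.
#'
#' @param candidates `GRanges` of planted candidates.
#' @param active Integer/logical vector marking active candidates.
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return A `signal_track`.
#' @export
generate_atac_track <- function(candidates, active,
                                cfg = synthetic_config(), seed = 1L) {
  rng <- local_rng(seed)
  sl <- synthetic_seqlengths(cfg)
  parts <- list()
  for (ch in names(sl)) {
    n_blocks <- ceiling(sl[[ch]] / cfg$background_block)
    vals <- abs(with_rng(rng, stats::rnorm(n_blocks, 0,
                                           cfg$background_noise_sd)))
    s <- (seq_len(n_blocks) - 1L) * cfg$background_block + 1L
    e <- pmin(s + cfg$background_block - 1L, sl[[ch]])
    parts[[length(parts) + 1L]] <-
      GRanges(ch, IRanges(s, e), score = vals, seqlengths = sl)
  }
  act <- candidates[as.logical(active)]
  if (length(act) > 0L && cfg$atac_peak_height > 0) {
    half <- as.integer(ceiling(4 * cfg$atac_peak_sd))
    for (i in seq_along(act)) {
      ch <- as.character(seqnames(act[i]))
      center <- start(act[i]) + GenomicRanges::width(act[i]) %/% 2L
      pos <- max(1L, center - half):min(sl[[ch]], center + half)
      bump <- cfg$atac_peak_height *
        exp(-((pos - center)^2) / (2 * cfg$atac_peak_sd^2))
      parts[[length(parts) + 1L]] <-
        GRanges(ch, IRanges(pos, pos), score = bump, seqlengths = sl)
    }
  }
  gr <- suppressWarnings(do.call(c, parts))
  signal_track(gr, seqlengths = sl)   # coverage() sums overlapping scores
}

#' Generate in vivo peaks centered on active candidates
#'
#' One peak of width `2 * invivo_peak_halfwidth + 1` per active candidate,
#' optionally jittered by up to `peak_jitter` bp; no peaks elsewhere.
#'
#' @inheritParams generate_atac_track
#' @return A sorted `GRanges` of peaks (empty when nothing is active).
#' @export
generate_invivo_peaks <- function(candidates, active,
                                  cfg = synthetic_config(), seed = 1L) {
  rng <- local_rng(seed)
  act <- candidates[as.logical(active)]
  if (length(act) == 0L) {
    return(GRanges(seqlengths = synthetic_seqlengths(cfg)))
  }
  center <- start(act) + GenomicRanges::width(act) %/% 2L
  if (cfg$peak_jitter > 0L) {
    center <- center + with_rng(rng,
      sample.int(2L * cfg$peak_jitter + 1L, length(act), TRUE)) -
      cfg$peak_jitter - 1L
  }
  hw <- cfg$invivo_peak_halfwidth
  peaks <- GRanges(seqnames(act),
                   IRanges(start = pmax(1L, center - hw), end = center + hw),
                   seqlengths = synthetic_seqlengths(cfg))
  GenomicRanges::sort(peaks, ignore.strand = TRUE)
}

#' Generate a complete synthetic study on disk
#'
#' Orchestrates genome, candidates, accessibility track and in vivo peaks,
#' writing standard formats: `genome.fa`, `candidates.bed`, `atac.bedGraph`,
#' `peaks.bed`, plus `truth.tsv` (the hidden labels — for validation only,
#' never a pipeline input) and `manifest.json` (config + seed; re-running
#' from it reproduces the outputs byte for byte).
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return List of file paths plus the in-memory `candidates`, `truth`,
#'   `track`, `peaks` and `genome` objects.
#' @export
generate_synthetic_study <- function(cfg = synthetic_config(), seed = 1L,
                                     dir = tempfile("g4study")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  genome <- generate_genome(cfg, seed)
  planted <- plant_candidates(genome, cfg, seed + 1L)
  track <- generate_atac_track(planted$candidates, planted$truth$active,
                               cfg, seed + 2L)
  peaks <- generate_invivo_peaks(planted$candidates, planted$truth$active,
                                 cfg, seed + 3L)
  paths <- list(
    genome_fa = file.path(dir, "genome.fa"),
    candidates_bed = file.path(dir, "candidates.bed"),
    atac_bedgraph = file.path(dir, "atac.bedGraph"),
    peaks_bed = file.path(dir, "peaks.bed"),
    truth_tsv = file.path(dir, "truth.tsv"),
    manifest_json = file.path(dir, "manifest.json"))
  writeXStringSet(planted$genome, paths$genome_fa)
  write_bed(planted$candidates, paths$candidates_bed)
  cov_gr <- as(track$cov, "GRanges")
  cov_gr <- cov_gr[cov_gr$score != 0]
  rtracklayer::export(cov_gr, paths$atac_bedgraph, format = "bedGraph")
  write_bed(peaks, paths$peaks_bed)
  utils::write.table(planted$truth, paths$truth_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- c(unclass(cfg), list(seed = seed))
  jsonlite::write_json(manifest, paths$manifest_json, auto_unbox = TRUE,
                       digits = NA)
  c(list(dir = dir), paths,
    list(genome = planted$genome, candidates = planted$candidates,
         truth = planted$truth, track = track, peaks = peaks))
}
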