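# Core model: BED/bedGraph I/O, coverage tracks, window densities.

test_that("read_bed parses BED6 with the 0-based half-open convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tx\t0\t+", "chr2\t5\t6\ty\t3\t-"), path)
  gr <- read_bed(path)
  expect_length(gr, 2L)
  expect_equal(GenomicRanges::start(gr), c(101L, 6L))  # GRanges is 1-based
  expect_equal(GenomicRanges::end(gr), c(200L, 6L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(S4Vectors::mcols(gr)$name, c("x", "y"))
  expect_equal(S4Vectors::mcols(gr)$score, c(0, 3))
})

test_that("read_bed rejects inverted coordinates and malformed lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t100", path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\t1\t2\ta\t0\t+", "chr1\t5"), path)
  expect_error(read_bed(path), "line 2")
})

test_that("BED round-trip of random intervals is lossless", {
  set.seed(42)
  n <- 100L
  start <- sample.int(100000L, n)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                   start = start, end = start + sample.int(500L, n),
                   name = sprintf("iv%03d", seq_len(n)),
                   score = sample(0:50, n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$score <- df$score
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))
  expect_equal(S4Vectors::mcols(back)$name, df$name)
  expect_equal(S4Vectors::mcols(back)$score, as.numeric(df$score))
})

test_that("read_bed agrees with the rtracklayer importer", {
  skip_if_not_installed("rtracklayer")
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta\t5\t+",
               "chr1\t500\t750\tb\t9\t-",
               "chr2\t0\t10\tc\t1\t+"), path)
  mine <- read_bed(path)
  ref <- rtracklayer::import(path, format = "bed")
  expect_equal(GenomicRanges::start(mine), GenomicRanges::start(ref))
  expect_equal(GenomicRanges::end(mine), GenomicRanges::end(ref))
  expect_equal(as.character(GenomicRanges::strand(mine)),
               as.character(GenomicRanges::strand(ref)))
  expect_equal(S4Vectors::mcols(mine)$score, S4Vectors::mcols(ref)$score)
})

test_that("bedGraph expansion sums overlapping lines per base", {
  sizes <- c(chr1 = 100L)
  plus <- withr::local_tempfile(fileext = ".bg")
  minus <- withr::local_tempfile(fileext = ".bg")
  writeLines(c("chr1 10 13 2.0", "chr1\t10\t11\t1.0"), plus)  # mixed separators
  writeLines(character(0), minus)
  track <- read_bedgraph_pair(plus, minus, sizes)
  expect_equal(as.numeric(track$plus$chr1[11:13]), c(3, 2, 2))  # pos 10 = 2+1
  expect_equal(sum(track$minus$chr1), 0)
  expect_equal(track_total(track), 7)
})

test_that("bedGraph read rejects unknown chromosomes and negative values", {
  sizes <- c(chr1 = 100L)
  p <- withr::local_tempfile(); m <- withr::local_tempfile()
  writeLines("chrX\t0\t5\t1", p); writeLines(character(0), m)
  expect_error(read_bedgraph_pair(p, m, sizes), "unknown chromosome")
  writeLines("chr1\t0\t5\t-1", p)
  expect_error(read_bedgraph_pair(p, m, sizes), "negative")
})

test_that("bedGraph round-trip conserves total signal and per-base values", {
  set.seed(11)
  sizes <- c(chr1 = 5000L, chr2 = 2000L)
  track <- coverage_track(sizes)
  for (chrom in names(sizes)) {
    for (s in c("+", "-")) {
      pos <- sample.int(sizes[[chrom]], 200L) - 1L
      track <- add_sites(track, chrom, pos, s,
                         sample(1:5, 200L, replace = TRUE))
    }
  }
  p <- withr::local_tempfile(); m <- withr::local_tempfile()
  write_bedgraph_pair(track, p, m)
  back <- read_bedgraph_pair(p, m, sizes)
  expect_equal(track_total(back), track_total(track))
  expect_identical(as.numeric(back$plus$chr1), as.numeric(track$plus$chr1))
  expect_identical(as.numeric(back$minus$chr2), as.numeric(track$minus$chr2))
})

test_that("window_density divides strand-specific sums by window length", {
  sizes <- c(chr1 = 1000L)
  track <- coverage_track(sizes)
  track <- add_sites(track, "chr1", 100:399, "+", 2)  # 300 bp x 2 = 600 reads
  expect_equal(window_density(track, "chr1", 100, 400, "+"), 2)
  expect_equal(window_density(track, "chr1", 100, 400, "-"), 0)
  expect_error(window_density(track, "chr1", 100, 100), "length")
})

test_that("window_density equals brute-force summation and recombines by
           length-weighted mean over a split", {
  set.seed(5)
  sizes <- c(chr1 = 400L)
  iv <- data.frame(start = sample(0:350, 30L, replace = TRUE))
  iv$end <- iv$start + sample(1:50, 30L, replace = TRUE)
  iv$end <- pmin(iv$end, 400L)
  iv$value <- sample(1:4, 30L, replace = TRUE)
  p <- withr::local_tempfile(); m <- withr::local_tempfile()
  writeLines(paste("chr1", iv$start, iv$end, iv$value, sep = "\t"), p)
  writeLines(character(0), m)
  track <- read_bedgraph_pair(p, m, sizes)

  for (win in list(c(0L, 400L), c(37L, 210L), c(100L, 101L))) {
    expect_equal(
      window_density(track, "chr1", win[1L], win[2L], "+"),
      oracle_window_sum(iv, win[1L], win[2L]) / (win[2L] - win[1L])
    )
  }
  # split invariance: density of the union is the length-weighted mean
  d_all <- window_density(track, "chr1", 40, 360, "+")
  d1 <- window_density(track, "chr1", 40, 150, "+")
  d2 <- window_density(track, "chr1", 150, 360, "+")
  expect_equal(d_all, (d1 * 110 + d2 * 210) / 320)
})

test_that("read_fasta returns named RNA-alphabet strings", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">rna1", "ACGTACGT", ">rna2 description", "ggcc"), path)
  seqs <- read_fasta(path)
  expect_equal(unname(seqs[1L]), "ACGUACGU")
  expect_equal(unname(seqs[2L]), "GGCC")
  expect_match(names(seqs)[1L], "rna1")
  dna <- read_fasta(path, as_rna = FALSE)
  expect_equal(unname(dna[1L]), "ACGTACGT")
})

test_that("ground-truth sidecars round-trip through JSON", {
  skip_if_not_installed("jsonlite")
  cfg <- sim_config(seed = 12, n_enhancers = 3L, chrom_length = 50000L)
  tab <- simulate_5prime_reads(cfg)
  path <- withr::local_tempfile(fileext = ".truth.json")
  write_truth_json(attr(tab, "truth"), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$tss, attr(tab, "truth")$tss)
  expect_equal(back$strand, attr(tab, "truth")$strand)
})

test_that("site tables round-trip through BED6 with score = count", {
  sites <- data.frame(chrom = "chr1", pos = c(5L, 99L, 1000L),
                      strand = c("+", "-", "+"), count = c(1, 30, 7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_site_table(sites, path)
  back <- read_site_table(path)
  expect_equal(back[order(back$pos), ]$pos, sort(sites$pos))
  expect_equal(sum(back$count), sum(sites$count))
})
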