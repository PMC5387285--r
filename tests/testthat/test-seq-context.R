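test_that("flank extraction follows the 1-based inclusive convention", {
  genome <- c(chr1 = "ACGTACGTAC")
  snp <- data.frame(chrom = "chr1", start = 5L, end = 5L)
  ctx <- extract_flanks(genome, snp, w = 3)
  expect_equal(ctx$left, "CGT")
  expect_equal(ctx$right, "CGT")
  # edge truncation
  ctx2 <- extract_flanks(genome, data.frame(chrom = "chr1", start = 1L,
                                            end = 1L), w = 5)
  expect_equal(ctx2$left, "")
  expect_equal(ctx2$right, "CGTAC")
  # insertion (start == end == k): left ends at k, right begins at k+1
  ins <- extract_flanks(genome, data.frame(chrom = "chr1", start = 4L,
                                           end = 4L), w = 2)
  expect_equal(ins$left, "CG")
  expect_equal(ins$right, "AC")
  # deletion spanning start..end: windows lie outside the deleted interval
  del <- extract_flanks(genome, data.frame(chrom = "chr1", start = 4L,
                                           end = 6L), w = 2)
  expect_equal(del$left, "CG")
  expect_equal(del$right, "GT")
  expect_error(extract_flanks(genome, data.frame(chrom = "chrX", start = 1L,
                                                 end = 1L), w = 2),
               "absent")
  expect_error(extract_flanks(genome, data.frame(chrom = "chr1", start = 0L,
                                                 end = 0L), w = 2),
               "start")
})

test_that("chrom aliasing maps MAF names onto contig names", {
  genome <- c(chr1 = "ACGTACGTAC")
  ctx <- extract_flanks(genome, data.frame(chrom = "1", start = 5L, end = 5L),
                        w = 2, chrom_alias = c("1" = "chr1"))
  expect_equal(ctx$left, "GT")
})

test_that("shorter windows are nested inside longer ones", {
  set.seed(9)
  genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                           collapse = ""))
  sites <- data.frame(chrom = "chr1", start = c(100L, 200L, 300L),
                      end = c(100L, 200L, 300L))
  big <- extract_flanks(genome, sites, w = 20)
  small <- extract_flanks(genome, sites, w = 5)
  expect_equal(substring(big$left, 16, 20), small$left)
  expect_equal(substring(big$right, 1, 5), small$right)
})

test_that("GC fraction excludes N and complements the AT fraction", {
  ctx <- toy_contexts(c("GGGGG", "ATATA", "AAGG", "NNN"),
                      c("CCCCC", "TATAT", "CCTT", "NNN"))
  gc <- gc_fraction(ctx)
  expect_equal(gc[1:3], c(1, 0, 0.5))
  expect_true(is.na(gc[4]))
  # gc + at = 1 on N-free contexts
  set.seed(1)
  seqs <- replicate(50, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                              collapse = ""))
  ctx2 <- toy_contexts(seqs, rev(seqs))
  at <- vapply(paste0(ctx2$left, ctx2$right), function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("A", "T"))
  }, numeric(1), USE.NAMES = FALSE)
  expect_equal(gc_fraction(ctx2) + at, rep(1, 50))
})

test_that("homopolymer profile finds per-base maximum runs per side", {
  ctx <- toy_contexts(c("ACGT", "AAAAA", ""),
                      c("GATTTTC", "", ""))
  prof <- homopolymer_profile(ctx)
  expect_equal(prof$max_run_T, c(4L, 0L, 0L))
  expect_equal(prof$max_run_A, c(1L, 5L, 0L))
  expect_equal(prof$overall_max, c(4L, 5L, 0L))
  # runs do not span the variant site: left TTT + right TTT stays 3
  both <- toy_contexts("ATTT", "TTTA")
  expect_equal(homopolymer_profile(both)$max_run_T, 3L)
})

test_that("homopolymer profile matches the regex oracle on random strings", {
  set.seed(77)
  seqs <- replicate(300, paste(
    sample(c("A", "C", "G", "T", "N"), sample(20:60, 1), TRUE,
           prob = c(0.3, 0.2, 0.2, 0.28, 0.02)), collapse = ""))
  ctx <- toy_contexts(seqs, rep("", length(seqs)))
  prof <- homopolymer_profile(ctx)
  for (b in c("A", "C", "G", "T")) {
    oracle <- vapply(seqs, max_run_oracle, integer(1), base = b,
                     USE.NAMES = FALSE)
    expect_equal(prof[[paste0("max_run_", b)]], oracle)
  }
})

test_that("long-run fraction counts strict exceedance within the window", {
  ctx <- toy_contexts(
    c("AAAAAA", "ACACAC", "GGGGGG", "ACGTAC"),
    c("", "", "", ""), w = 6)
  expect_equal(long_run_fraction(ctx, run_threshold = 5), 0.5)
  expect_equal(long_run_fraction(ctx, run_threshold = 0), 1)
  # a run 12 bp downstream is excluded at w = 10, included at w = 20
  far <- toy_contexts("ACGTACGTACGTACGTACGT",
                      paste0("ACGTACGTACGT", "TTTTTTTT"), w = 20)
  expect_equal(long_run_fraction(far, 5, w = 10), 0)
  expect_equal(long_run_fraction(far, 5, w = 20), 1)
  expect_error(long_run_fraction(far[0, ], 5), "no contexts")
})

test_that("long-run fraction is monotone in threshold and window", {
  cfg <- sim_config(seed = 21, genome_length = 20000L, homopolymer_boost = 2)
  genome <- generate_genome(cfg)
  sites <- data.frame(chrom = "chr1", start = seq(100L, 19000L, by = 95L))
  sites$end <- sites$start
  ctx <- extract_flanks(genome, sites, w = 50)
  fr_thr <- vapply(2:8, function(t) long_run_fraction(ctx, t), numeric(1))
  expect_true(all(diff(fr_thr) <= 0))
  fr_w <- vapply(c(10, 20, 30, 50), function(w)
    long_run_fraction(ctx, 5, w = w), numeric(1))
  expect_true(all(diff(fr_w) >= 0))
})

test_that("pooled t-test handles identical, shifted and degenerate input", {
  res <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  shifted <- two_sample_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  # closed form: t = (mean diff) / (s_p sqrt(2/3)) with s_p = 1
  expect_equal(shifted$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  deg <- two_sample_t(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  deg2 <- two_sample_t(c(1, 1), c(1, 1))
  expect_equal(deg2$p, 1)
})

test_that("rank-shift test is exact for small samples, approximate for large", {
  # U = 0: the 2 * (1 / C(6,3)) = 0.1 enumeration value
  expect_equal(rank_shift_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_shift_test(c(1, 2, 9), c(1, 2, 9)), 1, tolerance = 1e-6)
  set.seed(5)
  x <- stats::rnorm(1000)
  y <- stats::rnorm(1000, mean = 1)
  expect_lt(rank_shift_test(x, y), 1e-10)
})
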