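test_that("genome generation is deterministic and boost-sensitive", {
  cfg <- sim_config(seed = 3, genome_length = 50000L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  # boost 0: i.i.d. uniform base composition within 3 binomial sd
  cfg0 <- sim_config(seed = 3, genome_length = 100000L,
                     homopolymer_boost = 0)
  g0 <- generate_genome(cfg0)
  freq <- Biostrings::letterFrequency(g0, c("A", "C", "G", "T"))[1, ]
  se <- sqrt(0.25 * 0.75 * 100000)
  expect_true(all(abs(freq - 25000) < 3 * se))
  # larger boost lengthens homopolymer runs
  mean_max_run <- function(g) {
    s <- as.character(g)[[1]]
    starts <- seq(1L, nchar(s) - 50L, by = 50L)
    ctx <- toy_contexts(substring(s, starts, starts + 49L),
                        rep("", length(starts)), w = 50)
    mean(homopolymer_profile(ctx)$overall_max)
  }
  boosted <- generate_genome(sim_config(seed = 3, genome_length = 100000L,
                                        homopolymer_boost = 3))
  expect_gt(mean_max_run(boosted), mean_max_run(g0))
})

test_that("gene models pack alternating strands with internal splice sites", {
  cfg <- sim_config(seed = 5, n_genes = 10L, exons_per_gene = 3L)
  gm <- generate_gene_models(generate_genome(cfg), cfg)
  m <- gm$models
  expect_equal(length(unique(m$gene)), 10L)
  expect_equal(unname(table(m$strand[!duplicated(m$gene)])["+"]), 5L)
  # 3 exons -> 2 internal junctions -> 4 internal boundaries per gene
  per_gene <- vapply(split(m, m$gene), function(g) {
    ib <- batchbias:::.internal_boundaries(g$exon_start, g$exon_end)
    length(ib$starts) + length(ib$ends)
  }, integer(1))
  expect_true(all(per_gene == 4L))
  # genes do not overlap
  spans <- vapply(split(m, m$gene), function(g)
    c(min(g$exon_start), max(g$exon_end)), numeric(2))
  o <- order(spans[1, ])
  expect_true(all(spans[1, o][-1] > spans[2, o][-ncol(spans)]))
  expect_error(generate_gene_models(
    generate_genome(sim_config(seed = 1, genome_length = 1000L)),
    sim_config(seed = 1, genome_length = 1000L)), "fit")
})

test_that("planted acceptors carry the AG dinucleotide with a pyrimidine tract", {
  cfg <- sim_config(seed = 9, planted_context = "splice_acceptor",
                    n_genes = 10L, exons_per_gene = 3L)
  gm <- generate_gene_models(generate_genome(cfg), cfg)
  acc <- batchbias:::.acceptor_sites(gm$models)
  seqs <- as.character(gm$genome)
  for (i in seq_len(nrow(acc))) {
    if (acc$strand[i] == "+") {
      # variant position is the acceptor A; genome reads tract + TTAG | TT
      slice <- substring(seqs[[acc$chrom[i]]], acc$pos[i] - 10L,
                         acc$pos[i] + 3L)
      expect_match(slice, "^[CT]{8}TTAGTT$")
    } else {
      slice <- substring(seqs[[acc$chrom[i]]], acc$pos[i] - 3L,
                         acc$pos[i] + 10L)
      expect_match(slice, "^AACTAA[AG]{8}$")
    }
  }
})

test_that("cohorts have equal plates, parseable barcodes, determinism", {
  cfg <- sim_config(seed = 2, n_samples = 100L, n_plates = 5L)
  cohort <- generate_cohort(cfg)
  expect_equal(unname(table(cohort$plate_id)), rep(20L, 5L),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(cohort$barcode), 0L)
  expect_identical(generate_cohort(cfg), cohort)
  parsed <- parse_barcode(cohort$barcode)
  expect_equal(parsed$plate_id, cohort$plate_id)
})

test_that("planted variants have the configured carriers on one plate", {
  cfg <- sim_config(seed = 13, n_planted = 20L,
                    planted_enrichment = c(10L, 0L))
  b <- simulate_cohort(cfg)
  planted <- b$truth[b$truth$planted, ]
  expect_equal(nrow(planted), 20L)
  expect_equal(anyDuplicated(planted$key), 0L)
  plate_of <- stats::setNames(b$cohort$plate_id, b$cohort$barcode)
  for (i in seq_len(nrow(planted))) {
    carriers <- unique(b$dataset$variants$sample_barcode[
      variant_key(b$dataset) == planted$key[i]])
    expect_equal(length(carriers), 10L)
    expect_equal(unique(plate_of[carriers]), planted$batch_value[i],
                 ignore_attr = TRUE)
  }
})

test_that("reference alleles always match the generated genome", {
  cfg <- sim_config(seed = 17, background_rate = 20)
  b <- simulate_cohort(cfg)
  v <- unique(b$dataset$variants[, c("chrom", "start", "end", "ref_allele",
                                     "variant_type")])
  seqs <- as.character(b$genome)
  notins <- v[v$variant_type != "INS", ]
  got <- substring(seqs[notins$chrom], notins$start, notins$end)
  expect_equal(unname(got), notins$ref_allele)
})

test_that("homopolymer-planted sites sit next to runs longer than 5", {
  cfg <- sim_config(seed = 19, planted_context = "homopolymer",
                    homopolymer_boost = 2, n_planted = 15L)
  b <- simulate_cohort(cfg)
  planted_keys <- b$truth$key[b$truth$planted]
  sites <- parse_variant_key(planted_keys)
  ctx <- extract_flanks(b$genome, sites, w = 50)
  prof <- homopolymer_profile(ctx)
  expect_true(all(prof$overall_max > 5L))
})

test_that("generated MAFs pass QC and are byte-deterministic", {
  cfg <- sim_config(seed = 23)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$dataset$variants, b2$dataset$variants)
  expect_identical(b1$truth, b2$truth)
  qc <- qc_filter_datasets(list(b1$dataset))
  expect_equal(length(qc$kept), 1L)
  # splice-planted keys all classify as splicing
  cfgs <- sim_config(seed = 23, planted_context = "splice_acceptor",
                     n_genes = 30L, exons_per_gene = 4L, n_planted = 30L)
  bs <- simulate_cohort(cfgs)
  keys <- bs$truth$key[bs$truth$planted]
  region <- classify_region(parse_variant_key(keys), bs$models)
  expect_true(all(region == "splicing"))
  cls <- bs$dataset$variants$variant_classification[
    match(keys, variant_key(bs$dataset))]
  expect_true(all(cls == "splice_site"))
})

test_that("generator RNG use does not disturb the caller's stream", {
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(simulate_cohort(sim_config(seed = 7, background_rate = 30,
                                       n_samples = 100L, n_plates = 5L,
                                       n_planted = 0L)))
  expect_equal(stats::runif(1), before)
})
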