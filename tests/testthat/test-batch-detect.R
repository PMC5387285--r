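test_that("one-sided Fisher P matches the hypergeometric closed form", {
  # 3 of 3 carriers inside a batch of 5, cohort of 10:
  # P = C(3,3) C(7,2) / C(10,5) = 21/252
  expect_equal(fisher_exact_p(3, 2, 0, 5, alternative = "greater"),
               21 / 252, tolerance = 1e-12)
  # no carriers at all -> P = 1 under either alternative
  expect_equal(fisher_exact_p(0, 5, 0, 5, alternative = "greater"), 1)
  expect_equal(fisher_exact_p(0, 5, 0, 5, alternative = "two_sided"), 1)
})

test_that("Fisher P agrees with enumeration and with fisher.test", {
  set.seed(42)
  for (rep in 1:60) {
    N <- sample(4:30, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c <- sample(0:(N - a - b), 1); d <- N - a - b - c
    for (alt in c("greater", "two_sided")) {
      p <- fisher_exact_p(a, b, c, d, alternative = alt)
      expect_equal(p, fisher_oracle(a, b, c, d, alt), tolerance = 1e-7)
    }
    ft <- stats::fisher.test(matrix(c(a, c, b, d), 2),
                             alternative = "greater")$p.value
    expect_equal(fisher_exact_p(a, b, c, d, "greater"), ft,
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # permutation equivariance
  p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("contingency tables count samples, collapsing duplicate rows", {
  d <- toy_cohort_dataset(n = 10, n_plates = 2, carriers = c(1, 3, 5),
                          carrier_pos = 5000L)
  # plates assigned round-robin: odd sample indices on P01
  key <- "chr1:5000:G>A"
  asg <- batch_assignment(d, "plate")
  tab <- build_contingency(d, key, asg, "P01")
  expect_equal(unname(tab), c(3, 2, 0, 5))
  expect_error(build_contingency(d, key, asg, "NOPE"), "does not occur")
  # duplicated record for the same (variant, sample) counts once
  d$variants <- rbind(d$variants, toy_record(d$samples[1], start = 5000L,
                                             ref = "G", alt = "A"))
  expect_equal(unname(build_contingency(d, key, asg, "P01")), c(3, 2, 0, 5))
})

test_that("detection flags a plate-concentrated variant and applies filters", {
  # 100 samples over 5 plates of 20; one variant in 10 samples of plate P03
  carriers <- which(((seq_len(100) - 1L) %% 5L) + 1L == 3L)[1:10]
  d <- toy_cohort_dataset(n = 100, n_plates = 5, carriers = carriers)
  res <- detect_batch_biased(d)
  hit <- res[res$biased, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$variable, "plate")
  expect_equal(hit$batch_value, "P03")
  expect_equal(hit$key, "chr1:5000:G>A")
  expect_equal(unname(unlist(hit[, c("a", "b", "c", "d")])),
               c(10, 10, 0, 80))
  # closed-form check that the planted configuration clears the threshold
  expect_equal(hit$p, choose(20, 10) / choose(100, 10), tolerance = 1e-9)
  expect_lt(hit$p, 1e-5)
  expect_true(all(res$q >= res$p))
})

test_that("variants with fewer than 3 carriers in the batch are not tested", {
  carriers <- which(((seq_len(100) - 1L) %% 5L) + 1L == 3L)[1:2]
  d <- toy_cohort_dataset(n = 100, n_plates = 5, carriers = carriers)
  res <- suppressWarnings(detect_batch_biased(d))
  expect_false("chr1:5000:G>A" %in% res$key)
})

test_that("batches smaller than the minimum size are not tested", {
  # 25 samples over 5 plates of 5: no plate reaches the default minimum 6
  carriers <- which(((seq_len(25) - 1L) %% 5L) + 1L == 3L)
  d <- toy_cohort_dataset(n = 25, n_plates = 5, carriers = carriers)
  asg <- list(batch_assignment(d, "plate"))
  expect_warning(res <- detect_batch_biased(d, assignments = asg),
                 "no batch")
  expect_equal(nrow(res), 0L)
})

test_that("representative-batch collapsing keeps the largest nested ID", {
  mk <- function(value, keys, variable = "plate") {
    data.frame(maf = "m", variable = variable, batch_value = value,
               key = keys, a = 3L, b = 1L, c = 0L, d = 10L,
               p = 1e-7, q = 1e-6, biased = TRUE,
               stringsAsFactors = FALSE)
  }
  res <- rbind(mk("B1", c("v1", "v2", "v3", "v4")),
               mk("B2", c("v1", "v2", "v3")))
  kept <- select_representative_batches(res, overlap_threshold = 0.75)
  expect_setequal(unique(kept$batch_value), "B1")
  expect_setequal(kept$key, c("v1", "v2", "v3", "v4"))
  # disjoint sets are both kept
  res2 <- rbind(mk("B1", c("v1", "v2")), mk("B2", c("v3", "v4")))
  kept2 <- select_representative_batches(res2)
  expect_setequal(unique(kept2$batch_value), c("B1", "B2"))
  # idempotence, and a single ID passes through unchanged
  expect_equal(select_representative_batches(kept), kept)
  one <- mk("B9", c("v1", "v2"))
  expect_equal(select_representative_batches(one)$batch_value,
               one$batch_value)
  # collapsing links IDs across variables too (plate vs tss aliasing)
  res3 <- rbind(mk("0886", c("v1", "v2", "v3", "v4")),
                mk("AA", c("v1", "v2", "v3"), variable = "tss"))
  kept3 <- select_representative_batches(res3)
  expect_equal(unique(paste(kept3$variable, kept3$batch_value)),
               "plate 0886")
})

test_that("equal-sized collapsed sets break ties lexicographically", {
  mk <- function(value, keys) {
    data.frame(maf = "m", variable = "plate", batch_value = value,
               key = keys, a = 3L, b = 1L, c = 0L, d = 10L,
               p = 1e-7, q = 1e-6, biased = TRUE, stringsAsFactors = FALSE)
  }
  res <- rbind(mk("B2", c("v1", "v2")), mk("B1", c("v1", "v2")))
  kept <- select_representative_batches(res)
  expect_equal(unique(kept$batch_value), "B1")
})

test_that("cross-dataset recurrence counts datasets per key", {
  rec <- recurrent_variants(list(m1 = c("v1", "v2"), m2 = c("v1"),
                                 m3 = c("v1", "v3"), m4 = c("v9")))
  expect_equal(rec$key, "v1")
  expect_equal(rec$n_mafs, 3L)
  expect_equal(rec$mafs, "m1,m2,m3")
  none <- recurrent_variants(list(m1 = "a", m2 = "b"))
  expect_equal(nrow(none), 0L)
})

test_that("gene-level aggregation counts biased variants and min P", {
  d <- toy_cohort_dataset(n = 10)
  d$variants$gene_symbol <- "GENEX"
  res <- data.frame(
    maf = "m", variable = "plate", batch_value = "P01",
    key = variant_key(d)[1:2], a = 3L, b = 1L, c = 0L, d = 6L,
    p = c(1e-6, 1e-9), q = c(1e-5, 1e-8), biased = TRUE,
    stringsAsFactors = FALSE
  )
  agg <- gene_level_recurrence(res, d)
  expect_equal(agg$gene, "GENEX")
  expect_equal(agg$n_biased, 2L)
  expect_equal(agg$heat, 9)
  empty <- res[0, ]
  expect_equal(nrow(gene_level_recurrence(empty, d)), 0L)
})

test_that("SMG overlap is a plain intersection with containment check", {
  ov <- smg_overlap(c("A", "B"), c("B", "C"))
  expect_equal(ov$overlap, "B")
  expect_equal(smg_overlap(c("A", "B"), character(0))$overlap, character(0))
  expect_error(smg_overlap(c("A", "B"), c("B"), position_matched = "A"),
               "subset")
})
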