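test_that("read_maf parses a toy MAF, skips comments, preserves rows", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    "#version 1.0",
    paste("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type",
          "Variant_Classification", "Tumor_Sample_Barcode", sep = "\t"),
    paste("TP53", "chr17", "7578406", "7578406", "C", "T", "SNP",
          "missense", toy_barcode(1), sep = "\t"),
    paste("KRAS", "chr12", "25398284", "25398284", "C", "A", "SNP",
          "missense", toy_barcode(2), sep = "\t"),
    paste("TP53", "chr17", "7577120", "7577120", "G", "A", "SNP",
          "nonsense", toy_barcode(1), sep = "\t")
  ), path)
  d <- read_maf(path, name = "toy")
  expect_s3_class(d, "maf_dataset")
  expect_equal(nrow(d$variants), 3L)
  expect_equal(length(d$samples), 2L)
  expect_equal(d$variants$gene_symbol, c("TP53", "KRAS", "TP53"))
  expect_equal(d$variants$start[1], 7578406L)
})

test_that("read_maf reports the missing column by name", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(
    paste("Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
          "Reference_Allele", "Variant_Type", "Variant_Classification",
          "Tumor_Sample_Barcode", sep = "\t"),
    paste("TP53", "chr17", "1", "1", "C", "SNP", "missense",
          toy_barcode(1), sep = "\t")
  ), path)
  expect_error(read_maf(path), "alt_allele")
})

test_that("write_maf / read_maf round-trips records field-for-field", {
  d <- toy_cohort_dataset(n = 8, carriers = c(1, 2, 3))
  d$variants$extra_note <- paste0("x", seq_len(nrow(d$variants)))
  path <- withr::local_tempfile(fileext = ".maf")
  write_maf(d, path)
  d2 <- read_maf(path, name = d$name)
  expect_equal(d2$variants[, names(d$variants)], d$variants)
  expect_equal(d2$samples, d$samples)
})

test_that("parse_barcode decomposes plate, TSS and center fields", {
  b <- parse_barcode("TCGA-AA-1234-01A-01D-0886-08")
  expect_equal(b$plate_id, "0886")
  expect_equal(b$tss_id, "AA")
  expect_equal(b$center_id, "08")
  expect_equal(b$participant_id, "TCGA-AA-1234")
  expect_equal(parse_barcode("TCGA-XX-0001-01A-01D-0928-08")$plate_id,
               "0928")
  # trailing fields beyond the seventh are ignored
  expect_equal(parse_barcode("TCGA-AA-1234-01A-01D-0886-08-EXTRA")$center_id,
               "08")
  expect_error(parse_barcode("TCGA-AA-1234"), "fewer than 7")
})

test_that("parse_barcode is total on generated cohorts", {
  cfg <- sim_config(seed = 11, n_samples = 10000L, n_plates = 100L,
                    n_tss = 10L)
  cohort <- generate_cohort(cfg)
  parsed <- parse_barcode(cohort$barcode)
  expect_equal(nrow(parsed), 10000L)
  expect_equal(parsed$plate_id, cohort$plate_id)
  expect_equal(parsed$tss_id, cohort$tss_id)
})

test_that("qc filter drops indel-free, indel-flooded and small datasets", {
  no_indel <- toy_cohort_dataset(n = 150, name = "no_indel")
  small <- toy_cohort_dataset(n = 99, name = "small")
  small$variants <- rbind(small$variants,
                          toy_record(small$samples[1], start = 9000L,
                                     ref = "A", alt = "-", type = "DEL"))
  ok <- toy_cohort_dataset(n = 100, name = "ok")
  ok$variants <- rbind(ok$variants,
                       toy_record(ok$samples[1], start = 9000L,
                                  ref = "A", alt = "-", type = "DEL"))
  flooded <- toy_cohort_dataset(n = 150, name = "flooded")
  for (p in c(9100L, 9200L, 9300L)) {
    flooded$variants <- rbind(flooded$variants,
                              toy_record(flooded$samples[1], start = p,
                                         ref = "A", alt = "-", type = "DEL"))
  }
  res <- qc_filter_datasets(list(no_indel, small, ok, flooded),
                            max_indels = 2L)
  expect_setequal(res$dropped$name, c("no_indel", "small", "flooded"))
  expect_match(res$dropped$reason[res$dropped$name == "no_indel"],
               "no indels")
  expect_match(res$dropped$reason[res$dropped$name == "small"],
               "less than 100")
  res2 <- qc_filter_datasets(list(no_indel, small, ok))
  expect_equal(vapply(res2$kept, `[[`, character(1), "name"), "ok")
  # partition: kept and dropped cover the input exactly
  expect_equal(length(res2$kept) + nrow(res2$dropped), 3L)
})

test_that("variant keys round-trip through parse_variant_key", {
  d <- toy_cohort_dataset(n = 5)
  d$variants <- rbind(
    d$variants,
    toy_record(d$samples[1], start = 500L, ref = "-", alt = "G",
               type = "INS"),
    toy_record(d$samples[1], start = 600L, ref = "ATT", alt = "-",
               type = "DEL")
  )
  keys <- variant_key(d)
  pk <- parse_variant_key(keys)
  expect_equal(pk$chrom, d$variants$chrom)
  expect_equal(pk$start, d$variants$start)
  expect_equal(pk$end, d$variants$end)
  expect_equal(pk$ref_allele, d$variants$ref_allele)
  # insertion: end == start; multi-base deletion spans its bases
  expect_equal(pk$end[pk$ref_allele == "-"], pk$start[pk$ref_allele == "-"])
  expect_equal(pk$end[pk$ref_allele == "ATT"],
               pk$start[pk$ref_allele == "ATT"] + 2L)
})
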