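# Shared fixture builders: tiny hand-written cohorts and genomes used
# across test files. Everything is constructed in code.

toy_barcode <- function(i, plate = "0886", tss = "AA") {
  sprintf("TCGA-%s-%04d-01A-01D-%s-08", tss, i, plate)
}

# A minimal variant record row.
toy_record <- function(barcode, chrom = "chr1", start = 100L,
                       ref = "C", alt = "T", type = "SNP",
                       gene = "GENE1", classification = "missense") {
  end <- if (type == "DEL") start + nchar(ref) - 1L else start
  data.frame(
    gene_symbol = gene, chrom = chrom, start = start, end = end,
    ref_allele = ref, alt_allele = alt, variant_type = type,
    variant_classification = classification, sample_barcode = barcode,
    stringsAsFactors = FALSE
  )
}

# Cohort of n samples split over plates (round-robin), where `carriers`
# (sample indices) share one SNP; every sample also gets a private SNP so
# it appears in the MAF.
toy_cohort_dataset <- function(n = 100L, n_plates = 5L,
                               carriers = integer(0),
                               carrier_pos = 5000L, name = "toy") {
  plates <- sprintf("P%02d", ((seq_len(n) - 1L) %% n_plates) + 1L)
  barcodes <- vapply(seq_len(n),
                     function(i) toy_barcode(i, plate = plates[i]),
                     character(1))
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- toy_record(barcodes[i], start = 100L + i)
  }
  for (i in carriers) {
    rows[[length(rows) + 1L]] <- toy_record(barcodes[i],
                                            start = carrier_pos,
                                            ref = "G", alt = "A")
  }
  maf_dataset(do.call(rbind, rows), name = name)
}

# Flank-context frame built directly from strings.
toy_contexts <- function(left, right, w = max(nchar(c(left, right)))) {
  out <- data.frame(
    key = paste0("k", seq_along(left)), chrom = "chr1",
    start = 1000L + seq_along(left), end = 1000L + seq_along(left),
    left = left, right = right, stringsAsFactors = FALSE
  )
  attr(out, "w") <- as.integer(w)
  class(out) <- c("flank_context", class(out))
  out
}

# Exhaustive fixed-margin Fisher oracle: enumerate every table with the
# observed margins and sum hypergeometric point probabilities directly
# from factorials (independent of dhyper/phyper).
fisher_oracle <- function(a, b, c, d, alternative) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0L, n - (N - K)); hi <- min(K, n)
  pt <- function(x) {
    exp(lfactorial(K) - lfactorial(x) - lfactorial(K - x) +
          lfactorial(N - K) - lfactorial(n - x) - lfactorial(N - K - n + x) -
          (lfactorial(N) - lfactorial(n) - lfactorial(N - n)))
  }
  probs <- vapply(lo:hi, pt, numeric(1))
  obs <- pt(a)
  if (alternative == "greater") {
    sum(probs[(lo:hi) >= a])
  } else {
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
}

# Independent max-run oracle via regex match lengths.
max_run_oracle <- function(seq, base) {
  if (nchar(seq) == 0L) return(0L)
  m <- gregexpr(paste0(base, "+"), seq)[[1]]
  if (m[1] == -1L) 0L else max(attr(m, "match.length"))
}

hamming_kmer <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
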