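# Mutation-type classification, spectrum tables, region classification
# against a simple gene model, and strand-resolved tallies.

#' Mutation class labels
#'
#' Strand-collapsed substitution pairs (pyrimidine reference written
#' first) plus indel classes split by AT/GC content and direction.
#'
#' @return Character vector of the eleven class labels.
#' @export
mutation_classes <- function() {
  c("C>T/G>A", "C>A/G>T", "C>G/G>C", "T>A/A>T", "T>C/A>G", "T>G/A>C",
    "indel-AT-ins", "indel-AT-del", "indel-GC-ins", "indel-GC-del", "other")
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.sub_label <- function(ref, alt) {
  lab <- rep("other", length(ref))
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, .complement[ref], ref)
  a <- ifelse(pur, .complement[alt], alt)
  ok <- r %in% c("C", "T") & a %in% c("A", "C", "G", "T") & r != a
  pair <- paste0(r, ">", a)
  lut <- c("C>A" = "C>A/G>T", "C>G" = "C>G/G>C", "C>T" = "C>T/G>A",
           "T>A" = "T>A/A>T", "T>C" = "T>C/A>G", "T>G" = "T>G/A>C")
  lab[ok] <- lut[pair[ok]]
  lab
}

.indel_label <- function(bases, direction) {
  at <- vapply(strsplit(bases, "", fixed = TRUE),
               function(ch) sum(ch %in% c("A", "T")), integer(1))
  gc <- vapply(strsplit(bases, "", fixed = TRUE),
               function(ch) sum(ch %in% c("G", "C")), integer(1))
  lab <- rep("other", length(bases))
  lab[at > gc] <- paste0("indel-AT-", direction)
  lab[gc > at] <- paste0("indel-GC-", direction)
  lab
}

#' Classify variant records into mutation classes
#'
#' Substitutions are collapsed to pyrimidine-reference pairs, so a
#' `G>A` call and a `C>T` call fall into the same `C>T/G>A` class.
#' Insertions and deletions are labelled AT or GC by strict majority of
#' the inserted/deleted bases; an exact tie (or any non-ACGT substitution
#' allele) yields `"other"`.
#'
#' @param records Variant data frame or [maf_dataset()].
#' @return Character vector of class labels, one per record.
#' @examples
#' v <- data.frame(ref_allele = "G", alt_allele = "A", variant_type = "SNP")
#' classify_mutation(v)  # "C>T/G>A"
#' @export
classify_mutation <- function(records) {
  v <- if (inherits(records, "maf_dataset")) records$variants else records
  lab <- rep("other", nrow(v))
  snp <- v$variant_type == "SNP"
  lab[snp] <- .sub_label(toupper(v$ref_allele[snp]),
                         toupper(v$alt_allele[snp]))
  ins <- v$variant_type == "INS"
  lab[ins] <- .indel_label(toupper(v$alt_allele[ins]), "ins")
  del <- v$variant_type == "DEL"
  lab[del] <- .indel_label(toupper(v$ref_allele[del]), "del")
  lab
}

#' Mutation spectrum of a record set
#'
#' @param records Variant data frame or [maf_dataset()] (non-empty).
#' @return Data frame `class`, `count`, `fraction` over all eleven classes
#'   (zeros included); fractions sum to 1.
#' @export
spectrum_table <- function(records) {
  v <- if (inherits(records, "maf_dataset")) records$variants else records
  if (nrow(v) == 0L) stop("empty record set")
  lab <- factor(classify_mutation(v), levels = mutation_classes())
  cnt <- table(lab)
  data.frame(class = names(cnt), count = as.integer(cnt),
             fraction = as.numeric(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Enrichment of one mutation class between two record sets
#'
#' Two-sided Fisher's exact test on
#' `[[in-class, rest], [in-class, rest]]` for the biased vs unbiased
#' record sets.
#'
#' @param biased,unbiased Variant data frames or [maf_dataset()]s.
#' @param class A mutation class label from [mutation_classes()].
#' @return List with the 2x2 counts and `p`.
#' @export
compare_class_enrichment <- function(biased, unbiased, class) {
  stopifnot(class %in% mutation_classes())
  bl <- classify_mutation(biased)
  ul <- classify_mutation(unbiased)
  a <- sum(bl == class); b <- sum(bl != class)
  c <- sum(ul == class); d <- sum(ul != class)
  list(biased_in_class = a, biased_rest = b,
       unbiased_in_class = c, unbiased_rest = d,
       p = fisher_exact_p(a, b, c, d, alternative = "two_sided"))
}

#' Read a gene-model table
#'
#' Accepts either the long exon table written by this package (tab
#' separated, columns `gene`, `chrom`, `strand`, `exon_start`, `exon_end`,
#' 1-based inclusive) or BED12 (detected by a 12-column header-less file;
#' 0-based half-open block coordinates are converted).
#'
#' @param path Path to the table.
#' @return Gene-model data frame in long exon format, exons sorted within
#'   gene.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^gene\t", first)) {
    gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 12L) stop("gene-model file is neither the long exon ",
                              "table nor BED12")
    rows <- lapply(seq_len(nrow(bed)), function(i) {
      sizes <- as.integer(strsplit(bed[i, 11L], ",")[[1]])
      offs <- as.integer(strsplit(bed[i, 12L], ",")[[1]])
      data.frame(
        gene = bed[i, 4L], chrom = bed[i, 1L], strand = bed[i, 6L],
        exon_start = bed[i, 2L] + offs + 1L,
        exon_end = bed[i, 2L] + offs + sizes,
        stringsAsFactors = FALSE
      )
    })
    gm <- do.call(rbind, rows)
  }
  gm <- gm[order(gm$gene, gm$exon_start), ]
  rownames(gm) <- NULL
  gm
}

#' Write a gene-model table
#'
#' @param models Long-format gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  utils::write.table(models, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Internal exon boundaries of one gene: starts of all but the first exon
# and ends of all but the last (genomic order).
.internal_boundaries <- function(exon_start, exon_end) {
  o <- order(exon_start)
  s <- exon_start[o]; e <- exon_end[o]
  n <- length(s)
  if (n < 2L) return(list(starts = integer(0), ends = integer(0)))
  list(starts = s[-1L], ends = e[-n])
}

#' Classify variant positions relative to gene models
#'
#' Labels each site `splicing` (within `splice_window` bases of an
#' internal exon boundary, on the intron side), `exonic`, `intronic`
#' (inside the gene span but not exonic), or `intergenic`, with precedence
#' splicing > exonic > intronic > intergenic across overlapping genes.
#'
#' @param sites Data frame with `chrom` and `start` (the variant start is
#'   the classified position), e.g. from [parse_variant_key()].
#' @param models Gene-model data frame from [read_gene_models()] or
#'   [generate_gene_models()].
#' @param splice_window Intron-side distance from an internal exon
#'   boundary that counts as a splice site (default 2).
#' @return Character vector of region labels.
#' @export
classify_region <- function(sites, models, splice_window = 2L) {
  labels <- rep("intergenic", nrow(sites))
  rank <- c(intergenic = 0L, intronic = 1L, exonic = 2L, splicing = 3L)
  genes <- split(models, models$gene)
  for (g in genes) {
    on_chrom <- which(sites$chrom == g$chrom[1L])
    if (length(on_chrom) == 0L) next
    pos <- sites$start[on_chrom]
    span <- pos >= min(g$exon_start) & pos <= max(g$exon_end)
    if (!any(span)) next
    ib <- .internal_boundaries(g$exon_start, g$exon_end)
    lab <- rep(NA_character_, length(pos))
    lab[span] <- "intronic"
    in_exon <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(g))) {
      in_exon <- in_exon | (pos >= g$exon_start[i] & pos <= g$exon_end[i])
    }
    lab[span & in_exon] <- "exonic"
    spl <- rep(FALSE, length(pos))
    for (s in ib$starts) {
      spl <- spl | (pos >= s - splice_window & pos <= s - 1L)
    }
    for (e in ib$ends) {
      spl <- spl | (pos >= e + 1L & pos <= e + splice_window)
    }
    lab[spl] <- "splicing"
    upgrade <- !is.na(lab) & rank[lab] > rank[labels[on_chrom]]
    labels[on_chrom][upgrade] <- lab[upgrade]
  }
  labels
}

#' Strand-resolved mutation spectrum
#'
#' Tallies mutation classes (as written on the reference strand) by the
#' strand of the overlapping gene. Records overlapping no gene, or genes
#' on both strands, are excluded and their counts reported as attributes
#' `n_intergenic` and `n_ambiguous`.
#'
#' @param records Variant data frame or [maf_dataset()].
#' @param models Gene-model data frame.
#' @return Data frame `class`, `strand`, `count` with exclusion counts in
#'   attributes.
#' @export
strand_resolved_spectrum <- function(records, models) {
  v <- if (inherits(records, "maf_dataset")) records$variants else records
  spans <- do.call(rbind, lapply(split(models, models$gene), function(g) {
    data.frame(chrom = g$chrom[1L], from = min(g$exon_start),
               to = max(g$exon_end), strand = g$strand[1L],
               stringsAsFactors = FALSE)
  }))
  strand <- rep(NA_character_, nrow(v))
  ambiguous <- rep(FALSE, nrow(v))
  for (i in seq_len(nrow(spans))) {
    hit <- v$chrom == spans$chrom[i] & v$start >= spans$from[i] &
      v$start <= spans$to[i]
    conflict <- hit & !is.na(strand) & strand != spans$strand[i]
    ambiguous <- ambiguous | conflict
    strand[hit & is.na(strand)] <- spans$strand[i]
  }
  keep <- !is.na(strand) & !ambiguous
  n_intergenic <- sum(is.na(strand))
  n_ambiguous <- sum(ambiguous)
  lab <- factor(classify_mutation(v[keep, , drop = FALSE]),
                levels = mutation_classes())
  tab <- as.data.frame(table(class = lab, strand = factor(strand[keep],
                                                          levels = c("+", "-"))),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  attr(tab, "n_intergenic") <- n_intergenic
  attr(tab, "n_ambiguous") <- n_ambiguous
  tab
}

#' Carrier fraction of a variant in a dataset
#'
#' Unique carriers of the site divided by the cohort size; 0 for an
#' absent key.
#'
#' @param dataset A [maf_dataset()].
#' @param key Variant key(s).
#' @return Numeric vector in \[0, 1\].
#' @export
variant_recurrence_rate <- function(dataset, key) {
  stopifnot(inherits(dataset, "maf_dataset"))
  inc <- unique(data.frame(key = variant_key(dataset),
                           sample = dataset$variants$sample_barcode))
  cnt <- table(inc$key)
  n <- length(dataset$samples)
  as.numeric(ifelse(key %in% names(cnt), cnt[key], 0L)) / n
}

#' Records-per-sample mutation load of a dataset
#'
#' @param dataset A [maf_dataset()].
#' @return Total variant records divided by the number of samples.
#' @export
mutations_per_sample <- function(dataset) {
  nrow(dataset$variants) / length(dataset$samples)
}
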