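# Orchestration: simulate -> detect -> characterize -> phylo, writing
# tab-separated reports into an output directory. The functions are the
# pipeline surface; each stage is also usable on its own.

.log_msg <- function(...) message(sprintf("[batchbias] %s", sprintf(...)))

#' Run the simulation stage and write its outputs
#'
#' Writes the genome (FASTA), gene models, MAF, truth table and a config
#' echo into `out_dir`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param name Dataset name.
#' @return The [simulate_cohort()] bundle, invisibly, with file paths in
#'   `$paths`.
#' @export
run_simulate <- function(cfg, out_dir, name = "sim") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- simulate_cohort(cfg, name = name)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    models = file.path(out_dir, "gene_models.tsv"),
    maf = file.path(out_dir, paste0(name, ".maf")),
    truth = file.path(out_dir, paste0(name, ".truth.tsv")),
    config = file.path(out_dir, "config.tsv")
  )
  Biostrings::writeXStringSet(bundle$genome, paths$genome)
  write_gene_models(bundle$models, paths$models)
  write_maf(bundle$dataset, paths$maf)
  utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfgflat <- bundle$config
  cfgflat$spectrum_weights <- paste(names(cfgflat$spectrum_weights),
                                    cfgflat$spectrum_weights,
                                    sep = "=", collapse = ";")
  cfgflat$planted_weights <- paste(names(cfgflat$planted_weights),
                                   cfgflat$planted_weights,
                                   sep = "=", collapse = ";")
  cfgflat$sharing_range <- paste(cfgflat$sharing_range, collapse = "-")
  cfgflat$planted_enrichment <- paste(cfgflat$planted_enrichment,
                                      collapse = "-")
  utils::write.table(
    data.frame(parameter = names(cfgflat),
               value = unlist(lapply(cfgflat, as.character))),
    paths$config, sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$paths <- paths
  invisible(bundle)
}

#' Run detection over one or more MAF datasets
#'
#' Applies dataset QC, tests every dataset with [detect_batch_biased()],
#' collapses near-duplicate batch IDs with
#' [select_representative_batches()], and writes per-dataset result TSVs
#' plus a pooled post-collapse biased-variant list. Counts at every filter
#' stage are logged.
#'
#' @param datasets List of [maf_dataset()] objects (or a single one).
#' @param out_dir Output directory.
#' @param params A [detection_params()].
#' @param qc Apply [qc_filter_datasets()] first (default `TRUE`).
#' @return List with `results` (per-dataset `batch_bias_result`),
#'   `representative` (per-dataset collapsed biased rows), `biased_keys`
#'   (per-dataset character vectors) and `dropped` (QC report).
#' @export
run_detect <- function(datasets, out_dir, params = detection_params(),
                       qc = TRUE) {
  if (inherits(datasets, "maf_dataset")) datasets <- list(datasets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dropped <- data.frame(name = character(0), reason = character(0))
  if (qc) {
    flt <- qc_filter_datasets(datasets)
    datasets <- flt$kept
    dropped <- flt$dropped
    if (nrow(dropped) > 0L) {
      utils::write.table(dropped, file.path(out_dir, "dropped_datasets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (length(datasets) == 0L) {
    stop("no dataset passes QC (", nrow(dropped), " dropped)")
  }
  results <- list(); representative <- list(); biased_keys <- list()
  for (d in datasets) {
    res <- detect_batch_biased(d, params = params)
    rep_res <- select_representative_batches(
      res, overlap_threshold = params$overlap_threshold)
    .log_msg("%s: %d tests, %d significant (P < %g), %d after collapsing",
             d$name, nrow(res), sum(res$biased), params$p_threshold,
             length(unique(rep_res$key)))
    write_bias_results(res, file.path(out_dir,
                                      paste0(d$name, ".bias_tests.tsv")))
    results[[d$name]] <- res
    representative[[d$name]] <- rep_res
    biased_keys[[d$name]] <- unique(rep_res$key)
  }
  pooled <- sort(unique(unlist(biased_keys, use.names = FALSE)))
  writeLines(pooled, file.path(out_dir, "biased_variants.txt"))
  list(results = results, representative = representative,
       biased_keys = biased_keys, dropped = dropped)
}

#' Characterize biased vs unbiased variants
#'
#' Emits the sequence-context comparisons for one dataset: mutation
#' spectra of the biased and unbiased sites, GC-content t-test, region
#' distribution with splice-site enrichment, homopolymer-run rank-shift
#' tests over several window sizes, long-run fractions, the
#' strand-resolved splice-site spectrum, and the splice-site PFM,
#' consensus and top enriched k-mers.
#'
#' @param dataset A [maf_dataset()].
#' @param biased_keys Character vector of biased variant keys.
#' @param genome Genome accessor.
#' @param models Gene-model table.
#' @param out_dir Output directory.
#' @param w Flank window per side for extraction (default 50).
#' @param gc_w Window per side for the GC comparison (default 10, i.e. 20
#'   flanking bases in total).
#' @param run_windows Window sizes for the homopolymer comparisons
#'   (default `c(10, 20, 30, 40, 50)`).
#' @param run_threshold Long-run threshold (default 5, "longer than 5").
#' @param k k-mer length for motif enrichment (default 6).
#' @param splice_window Splice-site distance (default 2).
#' @return List of the computed tables/statistics, invisibly written as
#'   TSVs under `out_dir`.
#' @export
run_characterize <- function(dataset, biased_keys, genome, models, out_dir,
                             w = 50L, gc_w = 10L,
                             run_windows = c(10L, 20L, 30L, 40L, 50L),
                             run_threshold = 5L, k = 6L, splice_window = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  keys <- unique(variant_key(dataset))
  biased_keys <- intersect(biased_keys, keys)
  if (length(biased_keys) == 0L) stop("no biased keys present in dataset")
  unbiased_keys <- setdiff(keys, biased_keys)
  sites <- parse_variant_key(keys)
  is_biased <- sites$key %in% biased_keys
  site_records <- dataset$variants[match(sites$key, variant_key(dataset)), ]

  # spectra -----------------------------------------------------------------
  spec_b <- spectrum_table(site_records[is_biased, ])
  spec_u <- spectrum_table(site_records[!is_biased, ])
  spec <- cbind(spec_b, fraction_unbiased = spec_u$fraction,
                count_unbiased = spec_u$count)
  names(spec)[2:3] <- c("count_biased", "fraction_biased")
  utils::write.table(spec, file.path(out_dir, "spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # GC ----------------------------------------------------------------------
  ctx <- extract_flanks(genome, sites, w = w)
  gc <- gc_fraction(.trim_contexts(ctx, gc_w))
  gc_test <- two_sample_t(gc[is_biased & !is.na(gc)],
                          gc[!is_biased & !is.na(gc)])

  # regions ------------------------------------------------------------------
  region <- classify_region(sites, models, splice_window = splice_window)
  region_tab <- as.data.frame(table(
    region = factor(region, c("splicing", "exonic", "intronic",
                              "intergenic")),
    group = factor(ifelse(is_biased, "biased", "unbiased"))),
    stringsAsFactors = FALSE)
  utils::write.table(region_tab, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  spl_b <- sum(region == "splicing" & is_biased)
  spl_u <- sum(region == "splicing" & !is_biased)
  splice_enrichment_p <- fisher_exact_p(
    spl_b, sum(is_biased) - spl_b, spl_u, sum(!is_biased) - spl_u,
    alternative = "greater")

  # homopolymer runs ---------------------------------------------------------
  prof_full <- homopolymer_profile(ctx)
  run_tests <- do.call(rbind, lapply(run_windows, function(wi) {
    prof <- homopolymer_profile(.trim_contexts(ctx, wi))
    data.frame(
      w = wi,
      rank_shift_p = rank_shift_test(prof$overall_max[is_biased],
                                     prof$overall_max[!is_biased]),
      long_run_fraction_biased =
        long_run_fraction(ctx[is_biased, ], run_threshold, w = wi),
      long_run_fraction_unbiased =
        long_run_fraction(ctx[!is_biased, ], run_threshold, w = wi)
    )
  }))
  utils::write.table(run_tests, file.path(out_dir, "homopolymer_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(prof_full, gc = gc_fraction(ctx), biased = is_biased),
    file.path(out_dir, "context_features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # strand-resolved splice-site spectrum ------------------------------------
  spl_records <- site_records[region == "splicing", , drop = FALSE]
  strand_tab <- if (nrow(spl_records) > 0L) {
    strand_resolved_spectrum(spl_records, models)
  } else {
    NULL
  }
  if (!is.null(strand_tab)) {
    utils::write.table(strand_tab, file.path(out_dir, "splice_strand.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # splice-site motif --------------------------------------------------------
  cls <- classify_mutation(site_records)
  fg_idx <- which(is_biased & region == "splicing" & cls == "T>A/A>T")
  motif <- NULL
  if (length(fg_idx) >= 5L) {
    mw <- 10L
    fg_ctx <- .trim_contexts(ctx[fg_idx, ], mw)
    bg_idx <- which(!is_biased)
    bg_ctx <- .trim_contexts(ctx[bg_idx, ], mw)
    strand <- .strand_at(sites[fg_idx, ], models)
    fg_win <- context_windows(fg_ctx, genome, revcomp = strand == "-")
    bg_win <- context_windows(bg_ctx, genome)
    pfm <- build_pfm(fg_win)
    enr <- kmer_enrichment(fg_win, bg_win, k = k)
    write_pfm(pfm, file.path(out_dir, "splice_pfm.tsv"))
    write_meme(pfm, file.path(out_dir, "splice_motif.meme"),
               name = "splice_acceptor")
    utils::write.table(utils::head(enr, 50L),
                       file.path(out_dir, "kmer_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    motif <- list(pfm = pfm, consensus = consensus_string(pfm),
                  kmers = enr)
  }

  stats_tab <- data.frame(
    statistic = c("gc_t", "gc_p", "splice_enrichment_p"),
    value = c(gc_test$t, gc_test$p, splice_enrichment_p)
  )
  utils::write.table(stats_tab, file.path(out_dir, "summary_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(spectrum = spec, gc_test = gc_test,
                 region_table = region_tab,
                 splice_enrichment_p = splice_enrichment_p,
                 homopolymer_tests = run_tests, strand_table = strand_tab,
                 motif = motif))
}

# strand of the gene overlapping each site (NA when none/ambiguous)
.strand_at <- function(sites, models) {
  spans <- do.call(rbind, lapply(split(models, models$gene), function(g) {
    data.frame(chrom = g$chrom[1L], from = min(g$exon_start),
               to = max(g$exon_end), strand = g$strand[1L],
               stringsAsFactors = FALSE)
  }))
  strand <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(spans))) {
    hit <- sites$chrom == spans$chrom[i] & sites$start >= spans$from[i] &
      sites$start <= spans$to[i]
    strand[hit & is.na(strand)] <- spans$strand[i]
  }
  strand
}

#' Before/after phylogeny comparison
#'
#' Builds Neighbor-Joining trees from Hamming distances on binary
#' mutation profiles, once on all variant sites and once excluding the
#' biased ones, and scores how strongly samples cluster by batch label in
#' each.
#'
#' @param dataset A [maf_dataset()].
#' @param biased_keys Character vector of biased variant keys to remove.
#' @param out_dir Output directory (two Newick files and a score table).
#' @param labels Named character vector sample -> batch label; defaults to
#'   the barcode plate ID.
#' @return List with `score_before`, `score_after`, `delta`, and the two
#'   trees.
#' @export
run_phylo <- function(dataset, biased_keys, out_dir, labels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(dataset$samples) < 3L) stop("need at least 3 samples")
  if (is.null(labels)) {
    bc <- parse_barcode(dataset$samples)
    labels <- stats::setNames(bc$plate_id, dataset$samples)
  }
  keys <- unique(variant_key(dataset))
  keep <- setdiff(keys, biased_keys)
  if (length(keep) == 0L) stop("removing biased keys leaves no variants")
  m_before <- binary_profiles(dataset, keys)
  m_after <- binary_profiles(dataset, keep)
  d_before <- hamming_distances(m_before)
  d_after <- hamming_distances(m_after)
  tr_before <- neighbor_joining(d_before)
  tr_after <- neighbor_joining(d_after)
  ape::write.tree(tr_before, file.path(out_dir, "tree_before.nwk"))
  ape::write.tree(tr_after, file.path(out_dir, "tree_after.nwk"))
  s_before <- batch_clustering_score(d_before, labels)
  s_after <- batch_clustering_score(d_after, labels)
  utils::write.table(
    data.frame(stage = c("before", "after"),
               batch_clustering_score = c(s_before, s_after)),
    file.path(out_dir, "clustering_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  .log_msg("clustering score before removal %.3f, after %.3f",
           s_before, s_after)
  list(score_before = s_before, score_after = s_after,
       delta = s_before - s_after,
       tree_before = tr_before, tree_after = tr_after)
}
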