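# Synthetic cohort generator: reference genome, gene models, barcoded
# samples, background variants and planted batch-biased variants with a
# ground-truth table. Every stage is deterministic under the config seed.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Generator stages derive distinct seeds
# from the config seed so outputs do not depend on call order.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stage_seed <- function(cfg, stage) {
  # distinct sub-streams per stage, kept well below 2^31
  (cfg$seed %% 10000019L) * 101L + stage
}

#' Simulation configuration
#'
#' Defines a synthetic tumor cohort: a random reference genome with a
#' tunable homopolymer tendency, non-overlapping multi-exon gene models on
#' alternating strands, a barcoded cohort with plate/TSS batch structure,
#' background somatic variants with a substitution spectrum dominated by
#' C>T/G>A and indels optionally concentrated near homopolymer runs, and
#' planted plate-associated variants in a chosen sequence context.
#'
#' @param seed Integer master seed; all stages derive their own
#'   sub-streams from it.
#' @param genome_length Total genome length in bases (default 100000).
#' @param n_contigs Number of contigs (default 1).
#' @param homopolymer_boost Non-negative weight added to repeating the
#'   previous base: the next base repeats with probability
#'   `boost / (4 + boost)` and is otherwise uniform, so 0 gives an i.i.d.
#'   uniform genome (default 1).
#' @param n_genes,exons_per_gene Gene-model shape (defaults 20 genes, 3
#'   exons each; at least 2 exons so internal splice sites exist).
#' @param n_samples,n_plates,n_tss Cohort shape: samples are assigned to
#'   plates round-robin (equal plate sizes) and to TSS codes at random
#'   (defaults 200 samples, 10 plates, 4 TSS).
#' @param background_rate Expected background variant records per sample
#'   (default 30).
#' @param spectrum_weights Named non-negative weights over
#'   [mutation_classes()] for background variants; the default is
#'   transition-dominated (C>T/G>A heaviest, T>G/A>C lightest) with a 15%
#'   indel load.
#' @param sharing_range Integer range; each background variant site is
#'   carried by a uniform draw from this many samples, plate-agnostic, so
#'   the batch null holds (default 1-3).
#' @param hp_indel_frac Fraction of background indels placed adjacent to a
#'   homopolymer run of length >= 4 (default 0.5).
#' @param n_planted Number of planted batch-biased variant sites
#'   (default 50).
#' @param planted_enrichment Integer pair `(carriers_in_batch,
#'   carriers_outside)` (default `c(10, 0)`).
#' @param planted_context `"random"`, `"homopolymer"` (site adjacent to a
#'   run longer than 5) or `"splice_acceptor"` (T>A at a planted acceptor
#'   `AG` with an upstream pyrimidine tract).
#' @param planted_weights Named weights over classes for planted variants
#'   in random/homopolymer contexts; default mirrors an artifact-heavy
#'   spectrum (G/C insertions and T>A/A>T substitutions).
#' @param splice_window Intron-side distance defining the splice-site
#'   label (default 2).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_contigs = 1L,
                       homopolymer_boost = 1,
                       n_genes = 20L,
                       exons_per_gene = 3L,
                       n_samples = 200L,
                       n_plates = 10L,
                       n_tss = 4L,
                       background_rate = 30,
                       spectrum_weights = NULL,
                       sharing_range = c(1L, 3L),
                       hp_indel_frac = 0.5,
                       n_planted = 50L,
                       planted_enrichment = c(10L, 0L),
                       planted_context = c("random", "homopolymer",
                                           "splice_acceptor"),
                       planted_weights = NULL,
                       splice_window = 2L) {
  planted_context <- match.arg(planted_context)
  if (is.null(spectrum_weights)) {
    spectrum_weights <- c(
      "C>T/G>A" = 0.45, "C>A/G>T" = 0.09, "C>G/G>C" = 0.08,
      "T>A/A>T" = 0.07, "T>C/A>G" = 0.12, "T>G/A>C" = 0.04,
      "indel-AT-ins" = 0.02, "indel-AT-del" = 0.06,
      "indel-GC-ins" = 0.03, "indel-GC-del" = 0.04
    )
  }
  if (is.null(planted_weights)) {
    planted_weights <- c("indel-GC-ins" = 0.5, "T>A/A>T" = 0.5)
  }
  stopifnot(
    genome_length >= 1000L, n_contigs >= 1L, homopolymer_boost >= 0,
    exons_per_gene >= 2L, n_samples >= n_plates, n_plates >= 1L,
    all(spectrum_weights >= 0), sum(spectrum_weights) > 0,
    length(sharing_range) == 2L, sharing_range[1] >= 1L,
    sharing_range[2] >= sharing_range[1],
    length(planted_enrichment) == 2L, planted_enrichment[1] >= 1L,
    planted_enrichment[2] >= 0L
  )
  if (n_planted > 0L &&
      planted_enrichment[1] > floor(n_samples / n_plates)) {
    stop("carriers_in_batch exceeds the plate size")
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         n_contigs = as.integer(n_contigs),
         homopolymer_boost = homopolymer_boost,
         n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         n_samples = as.integer(n_samples), n_plates = as.integer(n_plates),
         n_tss = as.integer(n_tss), background_rate = background_rate,
         spectrum_weights = spectrum_weights,
         sharing_range = as.integer(sharing_range),
         hp_indel_frac = hp_indel_frac,
         n_planted = as.integer(n_planted),
         planted_enrichment = as.integer(planted_enrichment),
         planted_context = planted_context,
         planted_weights = planted_weights,
         splice_window = as.integer(splice_window)),
    class = "sim_config"
  )
}

#' Generate a random reference genome
#'
#' First-order Markov base sampler: each base repeats the previous one
#' with probability `boost / (4 + boost)` and is otherwise drawn uniformly
#' from A/C/G/T, so `homopolymer_boost = 0` yields an i.i.d. uniform
#' genome and larger values lengthen homopolymer runs.
#'
#' @param cfg A [sim_config()].
#' @return A `Biostrings::DNAStringSet` with contigs `chr1`, `chr2`, ...
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bases <- c("A", "C", "G", "T")
  r <- cfg$homopolymer_boost / (4 + cfg$homopolymer_boost)
  len <- rep(cfg$genome_length %/% cfg$n_contigs, cfg$n_contigs)
  len[1L] <- len[1L] + cfg$genome_length %% cfg$n_contigs
  with_seed(.stage_seed(cfg, 1L), {
    seqs <- vapply(len, function(L) {
      draw <- sample.int(4L, L, replace = TRUE)
      rep_prev <- stats::runif(L) < r
      rep_prev[1L] <- FALSE
      # each repeated position copies the most recent fresh draw
      src <- cummax(ifelse(rep_prev, 0L, seq_len(L)))
      paste(bases[draw[src]], collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(
      seqs, paste0("chr", seq_len(cfg$n_contigs))))
  })
}

# positions of the starts of all maximal runs of length >= min_len
.run_table <- function(seq_char) {
  r <- rle(strsplit(seq_char, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  data.frame(base = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Generate gene models (and plant splice-acceptor motifs)
#'
#' Packs `n_genes` non-overlapping genes with `exons_per_gene` exons each
#' onto the genome, on alternating strands, leaving intergenic gaps. When
#' `planted_context = "splice_acceptor"`, every internal splice acceptor
#' is rewritten in the genome in transcript orientation as a pyrimidine
#' tract followed by `TTAGTT` (the `AG` being the acceptor dinucleotide
#' and `TT` the first exonic bases), reverse-complemented for minus-strand
#' genes.
#'
#' @param genome Genome from [generate_genome()].
#' @param cfg A [sim_config()].
#' @return List with `models` (long exon table: `gene`, `chrom`, `strand`,
#'   `exon_start`, `exon_end`) and `genome` (possibly edited).
#' @export
generate_gene_models <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  exon_len <- 150L
  intron_len <- 300L
  gap <- 400L
  gene_len <- cfg$exons_per_gene * exon_len +
    (cfg$exons_per_gene - 1L) * intron_len
  contig_len <- Biostrings::width(genome)
  per_contig <- ceiling(cfg$n_genes / cfg$n_contigs)
  need <- per_contig * (gene_len + gap) + gap
  if (any(contig_len < need)) {
    stop("genes do not fit: need ", need, " bases per contig, have ",
         min(contig_len))
  }
  rows <- list()
  g <- 0L
  for (ci in seq_along(genome)) {
    at <- gap
    for (k in seq_len(per_contig)) {
      if (g >= cfg$n_genes) break
      g <- g + 1L
      strand <- if (g %% 2L == 1L) "+" else "-"
      starts <- at + (seq_len(cfg$exons_per_gene) - 1L) *
        (exon_len + intron_len)
      rows[[g]] <- data.frame(
        gene = sprintf("GENE%03d", g), chrom = names(genome)[ci],
        strand = strand, exon_start = starts,
        exon_end = starts + exon_len - 1L, stringsAsFactors = FALSE
      )
      at <- at + gene_len + gap
    }
  }
  models <- do.call(rbind, rows)
  if (cfg$planted_context == "splice_acceptor") {
    genome <- with_seed(.stage_seed(cfg, 2L),
                        .plant_acceptor_motifs(genome, models))
  }
  list(models = models, genome = genome)
}

# Rewrite every internal acceptor in transcript orientation:
#   [8 nt pyrimidine tract] T T A G | T T (exon)
# For a plus-strand gene the acceptor is an internal exon start s:
# genome[s-4..s+1] <- "TTAGTT", genome[s-12..s-5] <- tract (T 75% / C 25%).
# For a minus-strand gene it is an internal exon end e, reverse-
# complemented: genome[e-1..e+4] <- "AACTAA", genome[e+5..e+12] <- tract'.
.plant_acceptor_motifs <- function(genome, models) {
  seqs <- as.character(genome)
  for (gname in unique(models$gene)) {
    g <- models[models$gene == gname, ]
    ib <- .internal_boundaries(g$exon_start, g$exon_end)
    chrom <- g$chrom[1L]
    s <- seqs[[chrom]]
    tract <- function() paste(sample(c("T", "C"), 8L, replace = TRUE,
                                     prob = c(0.75, 0.25)), collapse = "")
    if (g$strand[1L] == "+") {
      for (es in ib$starts) {
        substr(s, es - 4L, es + 1L) <- "TTAGTT"
        substr(s, es - 12L, es - 5L) <- tract()
      }
    } else {
      for (ee in ib$ends) {
        substr(s, ee - 1L, ee + 4L) <- "AACTAA"
        substr(s, ee + 5L, ee + 12L) <- chartr("TC", "AG", tract())
      }
    }
    seqs[[chrom]] <- s
  }
  Biostrings::DNAStringSet(seqs)
}

#' Generate a barcoded cohort
#'
#' TCGA-style barcodes with plates assigned round-robin (equal plate
#' sizes) and TSS codes drawn at random.
#'
#' @param cfg A [sim_config()].
#' @return Data frame `barcode`, `plate_id`, `tss_id`, one row per sample.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(.stage_seed(cfg, 3L), {
    plate <- sprintf("A%03d", ((seq_len(cfg$n_samples) - 1L) %%
                                 cfg$n_plates) + 1L)
    tss_codes <- paste0("A", LETTERS[seq_len(cfg$n_tss)])
    tss <- sample(tss_codes, cfg$n_samples, replace = TRUE)
    barcode <- paste("TCGA", tss, sprintf("%04d", seq_len(cfg$n_samples)),
                     "01A", "01D", plate, "08", sep = "-")
    data.frame(barcode = barcode, plate_id = plate, tss_id = tss,
               stringsAsFactors = FALSE)
  })
}

# ref-base pools a substitution class can be planted on
.class_ref_bases <- list(
  "C>T/G>A" = c("C", "G"), "C>A/G>T" = c("C", "G"), "C>G/G>C" = c("C", "G"),
  "T>A/A>T" = c("T", "A"), "T>C/A>G" = c("T", "A"), "T>G/A>C" = c("T", "A")
)
# pyrimidine-strand alt for each class, complemented for purine refs
.class_alt <- c("C>T/G>A" = "T", "C>A/G>T" = "A", "C>G/G>C" = "G",
                "T>A/A>T" = "A", "T>C/A>G" = "C", "T>G/A>C" = "G")

.alt_for <- function(class, ref) {
  alt_pyr <- .class_alt[class]
  ifelse(ref %in% c("A", "G"),
         unname(.complement[alt_pyr]), unname(alt_pyr))
}

# Draw a classification consistent with position and type.
.classification_for <- function(region, type) {
  n <- length(region)
  out <- rep("other", n)
  exonic <- region == "exonic"
  spl <- region == "splicing"
  out[spl] <- "splice_site"
  is_snp <- type == "SNP"
  out[exonic & is_snp] <- sample(
    c("missense", "silent", "nonsense", "stop_loss"),
    sum(exonic & is_snp), replace = TRUE, prob = c(0.68, 0.2, 0.1, 0.02))
  out[exonic & type == "INS"] <- sample(
    c("frameshift_ins", "inframe_ins"), sum(exonic & type == "INS"),
    replace = TRUE, prob = c(0.8, 0.2))
  out[exonic & type == "DEL"] <- sample(
    c("frameshift_del", "inframe_del"), sum(exonic & type == "DEL"),
    replace = TRUE, prob = c(0.8, 0.2))
  out
}

#' Generate a MAF dataset with planted batch-biased variants
#'
#' Background variant sites are placed uniformly over the genome with
#' classes drawn from `spectrum_weights` (indels optionally adjacent to
#' homopolymer runs); each site is carried by a uniform draw from
#' `sharing_range` samples chosen plate-agnostically, so background
#' carriers are null with respect to every batch variable. Planted sites
#' are placed in the configured context and assigned
#' `planted_enrichment[1]` carriers on one designated plate (plates cycle
#' over planted variants) plus `planted_enrichment[2]` carriers elsewhere.
#' Reference alleles always match the genome, and the variant
#' classification is consistent with the position (splice_site within
#' `splice_window` of an internal exon boundary, frameshift/inframe for
#' exonic indels, ...).
#'
#' @param genome Genome (use the possibly-edited genome returned by
#'   [generate_gene_models()]).
#' @param models Gene-model table from [generate_gene_models()].
#' @param cohort Cohort table from [generate_cohort()].
#' @param cfg A [sim_config()].
#' @param name Dataset name (default `"sim"`).
#' @return List with `dataset` (a [maf_dataset()]) and `truth` (data frame
#'   `key`, `planted`, `batch_variable`, `batch_value`, `context_type`;
#'   every planted site appears exactly once).
#' @export
generate_maf <- function(genome, models, cohort, cfg, name = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  genome_chars <- as.character(genome)
  with_seed(.stage_seed(cfg, 4L), {
    runs <- lapply(genome_chars, .run_table)
    edge <- 60L  # keep sites away from contig edges so flanks are full
    long_runs <- lapply(names(genome_chars), function(ch) {
      rt <- runs[[ch]]
      L <- nchar(genome_chars[[ch]])
      rt[rt$length > 5L & rt$start > edge & rt$end < L - edge, ]
    })
    med_runs <- lapply(names(genome_chars), function(ch) {
      rt <- runs[[ch]]
      L <- nchar(genome_chars[[ch]])
      rt[rt$length >= 4L & rt$start > edge & rt$end < L - edge, ]
    })
    names(long_runs) <- names(med_runs) <- names(genome_chars)
    used <- new.env(parent = emptyenv())  # occupied positions per contig
    take_pos <- function(chrom, pos) {
      tag <- paste0(chrom, ":", pos)
      if (exists(tag, envir = used)) return(FALSE)
      assign(tag, TRUE, envir = used)
      TRUE
    }

    draw_site <- function(class, context) {
      # returns chrom, pos, ref, alt, type for one site (or NULL to retry)
      chrom <- sample(names(genome_chars), 1L)
      L <- nchar(genome_chars[[chrom]])
      pos <- NA_integer_
      if (context == "homopolymer") {
        long <- long_runs[[chrom]]
        if (nrow(long) == 0L) {
          stop("no homopolymer run longer than 5 in the genome; ",
               "increase homopolymer_boost")
        }
        row <- long[sample.int(nrow(long), 1L), ]
        pos <- row$start - 1L  # site immediately 5' of the run
      } else if (grepl("^indel", class) && stats::runif(1) < cfg$hp_indel_frac) {
        med <- med_runs[[chrom]]
        if (nrow(med) > 0L) {
          row <- med[sample.int(nrow(med), 1L), ]
          pos <- row$start - 1L
        }
      }
      if (is.na(pos)) pos <- sample.int(L - 2L * edge, 1L) + edge
      ref_base <- substr(genome_chars[[chrom]], pos, pos)
      if (grepl("^indel", class)) {
        dir <- sub(".*-", "", class)
        at <- grepl("AT", class, fixed = TRUE)
        if (dir == "ins") {
          ins_base <- if (at) sample(c("A", "T"), 1L) else
            sample(c("G", "C"), 1L)
          site <- list(chrom = chrom, pos = pos, ref = "-", alt = ins_base,
                       type = "INS")
        } else {
          want <- if (at) c("A", "T") else c("G", "C")
          if (!ref_base %in% want) return(NULL)
          site <- list(chrom = chrom, pos = pos, ref = ref_base, alt = "-",
                       type = "DEL")
        }
      } else {
        if (!ref_base %in% .class_ref_bases[[class]]) return(NULL)
        site <- list(chrom = chrom, pos = pos, ref = ref_base,
                     alt = .alt_for(class, ref_base), type = "SNP")
      }
      if (!take_pos(site$chrom, site$pos)) return(NULL)
      site
    }

    draw_sites <- function(n, classes, context) {
      out <- vector("list", n)
      for (i in seq_len(n)) {
        site <- NULL
        tries <- 0L
        while (is.null(site)) {
          tries <- tries + 1L
          if (tries > 1000L) {
            stop("could not place a '", classes[i], "' site in context '",
                 context, "'; increase genome_length or homopolymer_boost")
          }
          site <- draw_site(classes[i], context)
        }
        out[[i]] <- site
      }
      out
    }

    # --- background sites -------------------------------------------------
    weights <- cfg$spectrum_weights
    mean_carriers <- mean(seq.int(cfg$sharing_range[1], cfg$sharing_range[2]))
    n_bg <- max(1L, round(cfg$n_samples * cfg$background_rate / mean_carriers))
    bg_classes <- sample(names(weights), n_bg, replace = TRUE,
                         prob = weights)
    bg_sites <- draw_sites(n_bg, bg_classes, "random")

    # --- planted sites ----------------------------------------------------
    pl_sites <- list()
    pl_classes <- character(0)
    pl_plate <- character(0)
    plates <- sort(unique(cohort$plate_id))
    if (cfg$n_planted > 0L) {
      pl_plate <- plates[((seq_len(cfg$n_planted) - 1L) %%
                            length(plates)) + 1L]
      if (cfg$planted_context == "splice_acceptor") {
        acc <- .acceptor_sites(models)
        if (nrow(acc) < cfg$n_planted) {
          stop("only ", nrow(acc), " internal acceptors available for ",
               cfg$n_planted, " planted splice variants; increase n_genes ",
               "or exons_per_gene")
        }
        acc <- acc[sample.int(nrow(acc), cfg$n_planted), ]
        pl_classes <- rep("T>A/A>T", cfg$n_planted)
        pl_sites <- lapply(seq_len(cfg$n_planted), function(i) {
          ref <- substr(genome_chars[[acc$chrom[i]]], acc$pos[i], acc$pos[i])
          take_pos(acc$chrom[i], acc$pos[i])
          list(chrom = acc$chrom[i], pos = acc$pos[i], ref = ref,
               alt = unname(ifelse(ref == "T", "A", "T")), type = "SNP")
        })
      } else {
        pl_classes <- sample(names(cfg$planted_weights), cfg$n_planted,
                             replace = TRUE, prob = cfg$planted_weights)
        if (cfg$planted_context == "homopolymer") {
          # indel-type planted artifacts next to long runs
          pl_classes <- rep("indel-GC-ins", cfg$n_planted)
        }
        pl_sites <- draw_sites(cfg$n_planted, pl_classes,
                               cfg$planted_context)
      }
    }

    # --- carriers ---------------------------------------------------------
    assign_bg_carriers <- function() {
      k <- sample(seq.int(cfg$sharing_range[1], cfg$sharing_range[2]),
                  n_bg, replace = TRUE)
      lapply(k, function(ki) sample(cohort$barcode, ki))
    }
    bg_carriers <- assign_bg_carriers()
    pl_carriers <- lapply(seq_along(pl_sites), function(i) {
      on_plate <- cohort$barcode[cohort$plate_id == pl_plate[i]]
      off_plate <- cohort$barcode[cohort$plate_id != pl_plate[i]]
      c(sample(on_plate, cfg$planted_enrichment[1]),
        if (cfg$planted_enrichment[2] > 0L)
          sample(off_plate, cfg$planted_enrichment[2]))
    })

    # --- assemble records -------------------------------------------------
    sites <- c(bg_sites, pl_sites)
    carriers <- c(bg_carriers, pl_carriers)
    site_df <- data.frame(
      chrom = vapply(sites, `[[`, character(1), "chrom"),
      pos = vapply(sites, `[[`, integer(1), "pos"),
      ref = vapply(sites, `[[`, character(1), "ref"),
      alt = vapply(sites, `[[`, character(1), "alt"),
      type = vapply(sites, `[[`, character(1), "type"),
      stringsAsFactors = FALSE
    )
    site_df$start <- site_df$pos
    site_df$end <- ifelse(site_df$type == "DEL",
                          site_df$pos + nchar(site_df$ref) - 1L, site_df$pos)
    region <- classify_region(
      data.frame(chrom = site_df$chrom, start = site_df$pos), models,
      splice_window = cfg$splice_window)
    site_df$classification <- .classification_for(region, site_df$type)
    site_df$gene <- .gene_at(site_df, models)
    site_df$key <- paste0(site_df$chrom, ":", site_df$start, ":",
                          site_df$ref, ">", site_df$alt)

    n_per_site <- lengths(carriers)
    idx <- rep(seq_len(nrow(site_df)), n_per_site)
    variants <- data.frame(
      gene_symbol = site_df$gene[idx],
      chrom = site_df$chrom[idx],
      start = site_df$start[idx],
      end = site_df$end[idx],
      ref_allele = site_df$ref[idx],
      alt_allele = site_df$alt[idx],
      variant_type = site_df$type[idx],
      variant_classification = site_df$classification[idx],
      sample_barcode = unlist(carriers),
      stringsAsFactors = FALSE
    )
    # order records by position for a tidy file; dataset semantics are
    # order-free
    variants <- variants[order(variants$chrom, variants$start,
                               variants$sample_barcode), ]
    rownames(variants) <- NULL
    # every sample must appear so the cohort size is recoverable from the
    # MAF; guarantee with a shared low-frequency sentinel? No: cohorts are
    # dense enough that every sample carries background variants; verify.
    missing <- setdiff(cohort$barcode, variants$sample_barcode)
    if (length(missing) > 0L) {
      stop(length(missing), " sample(s) carry no variant; increase ",
           "background_rate")
    }
    truth <- data.frame(
      key = site_df$key,
      planted = c(rep(FALSE, n_bg), rep(TRUE, length(pl_sites))),
      batch_variable = c(rep(NA_character_, n_bg),
                         rep("plate", length(pl_sites))),
      batch_value = c(rep(NA_character_, n_bg), pl_plate),
      context_type = c(rep("background", n_bg),
                       rep(cfg$planted_context, length(pl_sites))),
      stringsAsFactors = FALSE
    )
    list(dataset = maf_dataset(variants, name = name,
                               cancer_type = "synthetic"),
         truth = truth)
  })
}

# variant positions of plantable acceptors: the acceptor 'A' of the AG
# dinucleotide, in genome coordinates (s-2 for plus, e+2 for minus).
.acceptor_sites <- function(models) {
  out <- list()
  for (gname in unique(models$gene)) {
    g <- models[models$gene == gname, ]
    ib <- .internal_boundaries(g$exon_start, g$exon_end)
    if (g$strand[1L] == "+") {
      if (length(ib$starts) > 0L) {
        out[[gname]] <- data.frame(gene = gname, chrom = g$chrom[1L],
                                   strand = "+", pos = ib$starts - 2L,
                                   stringsAsFactors = FALSE)
      }
    } else {
      if (length(ib$ends) > 0L) {
        out[[gname]] <- data.frame(gene = gname, chrom = g$chrom[1L],
                                   strand = "-", pos = ib$ends + 2L,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

.gene_at <- function(site_df, models) {
  spans <- do.call(rbind, lapply(split(models, models$gene), function(g) {
    data.frame(gene = g$gene[1L], chrom = g$chrom[1L],
               from = min(g$exon_start), to = max(g$exon_end),
               stringsAsFactors = FALSE)
  }))
  gene <- rep("IGR", nrow(site_df))
  for (i in seq_len(nrow(spans))) {
    hit <- site_df$chrom == spans$chrom[i] & site_df$pos >= spans$from[i] &
      site_df$pos <= spans$to[i]
    gene[hit] <- spans$gene[i]
  }
  gene
}

#' Simulate a full study bundle
#'
#' Convenience wrapper running [generate_genome()],
#' [generate_gene_models()], [generate_cohort()] and [generate_maf()] in
#' order.
#'
#' @param cfg A [sim_config()].
#' @param name Dataset name.
#' @return List `genome`, `models`, `cohort`, `dataset`, `truth`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), name = "sim") {
  genome <- generate_genome(cfg)
  gm <- generate_gene_models(genome, cfg)
  cohort <- generate_cohort(cfg)
  maf <- generate_maf(gm$genome, gm$models, cohort, cfg, name = name)
  list(genome = gm$genome, models = gm$models, cohort = cohort,
       dataset = maf$dataset, truth = maf$truth, config = cfg)
}
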