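# Batch-bias detection: contingency tables, Fisher's exact test, BH FDR,
# the carrier/size filters, representative-batch collapsing, recurrence.

#' Detection parameters
#'
#' Tuning knobs for [detect_batch_biased()]. Defaults follow the stringent
#' regime appropriate for cohort-scale artifact screening: only batches
#' with more than 5 samples are testable, a variant must have at least 3
#' carriers inside the tested batch, significance is called at
#' P < 1e-5, and two batch IDs sharing more than 75% of their biased
#' variants are collapsed to one representative.
#'
#' @param min_batch_size Smallest testable batch (default 6 samples).
#' @param min_carriers_in_batch Minimum carriers of the variant inside the
#'   tested batch (default 3).
#' @param p_threshold Significance threshold on the Fisher P-value
#'   (default 1e-5).
#' @param overlap_threshold Shared-variant fraction above which two batch
#'   IDs are collapsed (default 0.75).
#' @param alternative `"greater"` (enrichment of carriers inside the batch,
#'   the default) or `"two_sided"`.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_batch_size = 6L, min_carriers_in_batch = 3L,
                             p_threshold = 1e-5, overlap_threshold = 0.75,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(min_batch_size >= 1, min_carriers_in_batch >= 1,
            p_threshold > 0, p_threshold <= 1,
            overlap_threshold > 0, overlap_threshold <= 1)
  structure(
    list(min_batch_size = as.integer(min_batch_size),
         min_carriers_in_batch = as.integer(min_carriers_in_batch),
         p_threshold = p_threshold,
         overlap_threshold = overlap_threshold,
         alternative = alternative),
    class = "detection_params"
  )
}

#' Batch assignments from barcodes or external tables
#'
#' Maps every sample of a dataset to one batch value per variable. The
#' barcode-encoded variables (`tss`, `plate`, `center`) are derived from
#' the sample barcode; any other sample-to-label mapping (BCR, shipment
#' date, clinical features) is supplied through `variable = "custom"` with
#' an explicit `mapping`.
#'
#' @param dataset A [maf_dataset()].
#' @param variable One of `"tss"`, `"plate"`, `"center"`, or `"custom"`.
#' @param mapping For `"custom"`: named character vector, names = sample
#'   barcodes, values = batch values; must cover every sample.
#' @param name Label used for the variable in results (defaults to
#'   `variable`).
#' @return List of class `batch_assignment` with `variable` and `mapping`
#'   (named character vector over all samples).
#' @export
batch_assignment <- function(dataset, variable = c("tss", "plate", "center",
                                                   "custom"),
                             mapping = NULL, name = NULL) {
  variable <- match.arg(variable)
  stopifnot(inherits(dataset, "maf_dataset"))
  samples <- dataset$samples
  if (variable == "custom") {
    if (is.null(mapping) || is.null(names(mapping))) {
      stop("custom assignment requires a named 'mapping' vector")
    }
    missing <- setdiff(samples, names(mapping))
    if (length(missing) > 0L) {
      stop("mapping lacks a value for ", length(missing), " sample(s), e.g. ",
           missing[1L])
    }
    map <- mapping[samples]
  } else {
    bc <- parse_barcode(samples)
    field <- switch(variable, tss = "tss_id", plate = "plate_id",
                    center = "center_id")
    map <- stats::setNames(bc[[field]], samples)
  }
  structure(
    list(variable = if (is.null(name)) variable else name,
         mapping = map),
    class = "batch_assignment"
  )
}

#' Sample-level 2x2 contingency table for one variant and one batch
#'
#' Counts samples (carriers deduplicated: a sample listed twice for the
#' same variant counts once) in and out of the batch, with and without the
#' variant: `a` carriers in batch, `b` non-carriers in batch, `c` carriers
#' outside, `d` non-carriers outside; `a+b` is the batch size and
#' `a+b+c+d` the cohort size.
#'
#' @param dataset A [maf_dataset()].
#' @param key A single variant key (`chrom:start:ref>alt`).
#' @param assignment A [batch_assignment()].
#' @param batch_value The batch value defining the "in batch" group.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(dataset, key, assignment, batch_value) {
  stopifnot(inherits(dataset, "maf_dataset"),
            inherits(assignment, "batch_assignment"))
  map <- assignment$mapping
  if (!batch_value %in% map) {
    stop("batch value '", batch_value, "' does not occur in the assignment")
  }
  carriers <- unique(dataset$variants$sample_barcode[
    variant_key(dataset) == key])
  in_batch <- names(map)[map == batch_value]
  a <- sum(carriers %in% in_batch)
  b <- length(in_batch) - a
  cc <- length(carriers) - a
  d <- length(map) - length(in_batch) - cc
  c(a = a, b = b, c = cc, d = d)
}

# Vectorized one-sided (greater) Fisher P for many tables at once:
# P(X >= a) with X ~ Hypergeometric(N = a+b+c+d, K = a+c, n = a+b).
.fisher_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Fisher's exact test P-value for a 2x2 table
#'
#' Exact hypergeometric P-value. The one-sided `"greater"` alternative is
#' the upper tail P(X >= a) conditioning on both margins; `"two_sided"`
#' sums the probabilities of all tables (with the same margins) whose point
#' probability does not exceed that of the observed table, within a
#' relative tolerance of 1e-7 to absorb floating-point noise at ties.
#'
#' @param a,b,c,d Non-negative cell counts: carriers in batch, non-carriers
#'   in batch, carriers outside, non-carriers outside. `a` may be a vector
#'   (then all four are recycled to a common length).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return P-value(s) in (0, 1].
#' @examples
#' fisher_exact_p(3, 2, 0, 5, alternative = "greater")  # 21/252
#' @export
fisher_exact_p <- function(a, b, c, d,
                           alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) stop("cells must be non-negative")
  if (alternative == "greater") {
    return(pmin(.fisher_greater(a, b, c, d), 1))
  }
  vapply(seq_len(n), function(i) {
    K <- a[i] + c[i]; nn <- a[i] + b[i]; N <- K + b[i] + d[i]
    lo <- max(0, nn - (N - K)); hi <- min(K, nn)
    probs <- stats::dhyper(lo:hi, K, N - K, nn)
    obs <- stats::dhyper(a[i], K, N - K, nn)
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]), preserving input order.
#'
#' @param p Numeric vector of P-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Detect batch-biased variants in one dataset
#'
#' For every combination of variant site, batch variable and batch value
#' with batch size at least `min_batch_size` and at least
#' `min_carriers_in_batch` carriers inside the batch, tests whether the
#' variant's carriers are enriched in the batch with Fisher's exact test.
#' BH-adjusted q-values are computed over all tests actually performed in
#' the dataset (all variables together); a test is flagged `biased` when
#' its raw P-value is below `p_threshold`.
#'
#' @param dataset A [maf_dataset()].
#' @param assignments List of [batch_assignment()] objects; defaults to the
#'   three barcode-derived variables (tss, plate, center).
#' @param params A [detection_params()].
#' @return Data frame of class `batch_bias_result`, one row per test,
#'   sorted by P ascending: `maf`, `variable`, `batch_value`, `key`, `a`,
#'   `b`, `c`, `d`, `p`, `q`, `biased`. Zero rows (with a warning) when no
#'   batch reaches the minimum size.
#' @export
detect_batch_biased <- function(dataset, assignments = NULL,
                                params = detection_params()) {
  stopifnot(inherits(dataset, "maf_dataset"),
            inherits(params, "detection_params"))
  if (is.null(assignments)) {
    assignments <- list(batch_assignment(dataset, "tss"),
                        batch_assignment(dataset, "plate"),
                        batch_assignment(dataset, "center"))
  }
  samples <- dataset$samples
  # Sample-level incidence: deduplicate (key, sample) pairs once.
  keys_all <- variant_key(dataset)
  inc <- unique(data.frame(key = keys_all,
                           sample = dataset$variants$sample_barcode,
                           stringsAsFactors = FALSE))
  n_total <- length(samples)
  out <- list()
  for (as_i in assignments) {
    map <- as_i$mapping[samples]
    batch_sizes <- table(map)
    ok_values <- names(batch_sizes)[batch_sizes >= params$min_batch_size]
    if (length(ok_values) == 0L) next
    # carriers per (key, batch value): a; carriers per key: a + c
    bf <- factor(map[inc$sample], levels = ok_values)
    kf <- factor(inc$key)
    carriers_total <- as.vector(table(kf))
    amat <- table(kf, bf)                      # keys x batch values
    hits <- which(amat >= params$min_carriers_in_batch, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    a <- as.vector(amat[hits])
    bv <- ok_values[hits[, 2L]]
    key <- levels(kf)[hits[, 1L]]
    bsz <- as.vector(batch_sizes[bv])
    K <- carriers_total[hits[, 1L]]
    b <- bsz - a
    cc <- K - a
    d <- n_total - bsz - cc
    p <- if (params$alternative == "greater") {
      pmin(.fisher_greater(a, b, cc, d), 1)
    } else {
      fisher_exact_p(a, b, cc, d, alternative = "two_sided")
    }
    out[[length(out) + 1L]] <- data.frame(
      maf = dataset$name, variable = as_i$variable, batch_value = bv,
      key = key, a = a, b = b, c = cc, d = d, p = p,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    warning("no batch reaches the minimum size or carrier filter; ",
            "no tests performed")
    res <- data.frame(maf = character(0), variable = character(0),
                      batch_value = character(0), key = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), p = numeric(0), q = numeric(0),
                      biased = logical(0), stringsAsFactors = FALSE)
    class(res) <- c("batch_bias_result", class(res))
    return(res)
  }
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  res$biased <- res$p < params$p_threshold
  res <- res[order(res$p, res$variable, res$batch_value, res$key), ]
  rownames(res) <- NULL
  class(res) <- c("batch_bias_result", class(res))
  res
}

#' Collapse near-duplicate batch IDs to representatives
#'
#' Two batch IDs (a `(variable, batch_value)` pair each) frequently flag
#' the same variants, e.g. when one plate maps onto one shipment date. If
#' the shared fraction of two IDs' biased-variant sets exceeds
#' `overlap_threshold`, the IDs are linked; within each connected component
#' only the ID with the largest biased-variant set is kept (ties broken by
#' lexicographically smallest ID). The overlap denominator is the smaller
#' set (containment), so a small ID nested in a large one collapses;
#' `denominator = "jaccard"` uses the union instead.
#'
#' @param results A `batch_bias_result` data frame (one detection run).
#' @param overlap_threshold Shared fraction above which IDs are linked
#'   (default 0.75).
#' @param denominator `"min"` (containment, default) or `"jaccard"`.
#' @return The rows of `results` restricted to biased rows of kept batch
#'   IDs (non-biased rows are dropped).
#' @export
select_representative_batches <- function(results, overlap_threshold = 0.75,
                                          denominator = c("min", "jaccard")) {
  denominator <- match.arg(denominator)
  biased <- results[results$biased, , drop = FALSE]
  if (nrow(biased) == 0L) return(biased)
  id <- paste(biased$variable, biased$batch_value, sep = ":")
  sets <- split(biased$key, id)
  ids <- sort(names(sets))
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        inter <- length(intersect(sets[[ids[i]]], sets[[ids[j]]]))
        den <- if (denominator == "min") {
          min(length(sets[[ids[i]]]), length(sets[[ids[j]]]))
        } else {
          length(union(sets[[ids[i]]], sets[[ids[j]]]))
        }
        if (den > 0 && inter / den > overlap_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- character(0)
  for (cmp in unique(comp)) {
    members <- ids[comp == cmp]
    sizes <- vapply(sets[members], length, integer(1))
    # largest set wins; ties -> lexicographically smallest ID
    best <- members[order(-sizes, members)][1L]
    keep <- c(keep, best)
  }
  out <- biased[id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variants flagged as biased in two or more datasets
#'
#' @param biased_keys_by_maf Named list: dataset name -> character vector of
#'   biased variant keys.
#' @return Data frame `key`, `n_mafs`, `mafs` (comma-joined), restricted to
#'   keys biased in at least 2 datasets, sorted by `n_mafs` descending.
#' @export
recurrent_variants <- function(biased_keys_by_maf) {
  stopifnot(is.list(biased_keys_by_maf), length(biased_keys_by_maf) >= 2L)
  long <- data.frame(
    maf = rep(names(biased_keys_by_maf), lengths(biased_keys_by_maf)),
    key = unlist(biased_keys_by_maf, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  long <- unique(long)
  tab <- table(long$key)
  rec <- names(tab)[tab >= 2L]
  if (length(rec) == 0L) {
    return(data.frame(key = character(0), n_mafs = integer(0),
                      mafs = character(0), stringsAsFactors = FALSE))
  }
  mafs <- vapply(rec, function(k) {
    paste(sort(long$maf[long$key == k]), collapse = ",")
  }, character(1))
  out <- data.frame(key = rec, n_mafs = as.integer(tab[rec]), mafs = mafs,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_mafs, out$key), ]
  rownames(out) <- NULL
  out
}

#' Gene-level aggregation of biased variants
#'
#' Maps each biased variant key to its gene symbol(s) through the variant
#' records and aggregates per gene and dataset: number of biased variants
#' and the heat value -log10(min P).
#'
#' @param results A `batch_bias_result` data frame (possibly row-bound over
#'   datasets).
#' @param records A variant data frame or [maf_dataset()] used to look up
#'   gene symbols by key; keys with no gene are counted under `"UNKNOWN"`
#'   with a warning.
#' @return Data frame `gene`, `maf`, `n_biased`, `min_p`, `heat`
#'   (= -log10(min_p)).
#' @export
gene_level_recurrence <- function(results, records) {
  v <- if (inherits(records, "maf_dataset")) records$variants else records
  biased <- results[results$biased, , drop = FALSE]
  if (nrow(biased) == 0L) {
    return(data.frame(gene = character(0), maf = character(0),
                      n_biased = integer(0), min_p = numeric(0),
                      heat = numeric(0), stringsAsFactors = FALSE))
  }
  lut <- unique(data.frame(key = variant_key(v), gene = v$gene_symbol,
                           stringsAsFactors = FALSE))
  gene <- lut$gene[match(biased$key, lut$key)]
  if (anyNA(gene)) {
    warning(sum(is.na(gene)), " biased key(s) with no gene symbol; ",
            "counted under UNKNOWN")
    gene[is.na(gene)] <- "UNKNOWN"
  }
  biased$gene <- gene
  # one row per (gene, maf); a key counted once per dataset
  uniq <- unique(biased[, c("gene", "maf", "key")])
  cnt <- stats::aggregate(key ~ gene + maf, data = uniq, FUN = length)
  names(cnt)[3L] <- "n_biased"
  minp <- stats::aggregate(p ~ gene + maf, data = biased, FUN = min)
  out <- merge(cnt, minp, by = c("gene", "maf"))
  names(out)[4L] <- "min_p"
  out$heat <- -log10(out$min_p)
  out <- out[order(out$gene, out$maf), ]
  rownames(out) <- NULL
  out
}

#' Overlap of biased genes with a significantly-mutated-gene list
#'
#' @param biased_genes Character set of genes carrying biased variants.
#' @param smg_list Character set of significantly mutated genes.
#' @param position_matched Optional subset of `biased_genes` whose biased
#'   site coincides exactly with a known mutation site; must be contained
#'   in the overlap.
#' @return List with `overlap` and `position_matched_overlap` (sorted).
#' @export
smg_overlap <- function(biased_genes, smg_list, position_matched = character(0)) {
  overlap <- sort(intersect(unique(biased_genes), unique(smg_list)))
  pm <- sort(unique(position_matched))
  if (!all(pm %in% overlap)) {
    stop("position-matched genes must be a subset of the SMG overlap")
  }
  list(overlap = overlap, position_matched_overlap = pm)
}

#' Write detection results as TSV
#'
#' Columns: maf, variable, batch_value, chrom, pos, ref, alt, a, b, c, d,
#' p, q, biased.
#'
#' @param results A `batch_bias_result` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias_results <- function(results, path) {
  pk <- parse_variant_key(results$key)
  out <- data.frame(
    maf = results$maf, variable = results$variable,
    batch_value = results$batch_value,
    chrom = pk$chrom, pos = pk$start, ref = pk$ref_allele,
    alt = pk$alt_allele,
    a = results$a, b = results$b, c = results$c, d = results$d,
    p = results$p, q = results$q, biased = results$biased,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare detected biased variants against a simulation truth table
#'
#' @param detected Character vector of detected biased variant keys.
#' @param truth Truth table from [generate_maf()] (data frame with `key`
#'   and `planted`).
#' @return Data frame with one row: `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`.
#' @export
evaluate_detection <- function(detected, truth) {
  planted <- unique(truth$key[truth$planted])
  detected <- unique(detected)
  tp <- length(intersect(detected, planted))
  fp <- length(setdiff(detected, planted))
  fn <- length(setdiff(planted, detected))
  data.frame(
    tp = tp, fp = fp, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
  )
}
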