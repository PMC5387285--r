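# Flanking-sequence context: window extraction, GC content, homopolymer
# runs, and the two-sample comparisons applied to these features.

.as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}

#' Extract flanking windows around variant sites
#'
#' For each variant site, returns the `w` reference bases immediately 5'
#' of `start` (`left`) and the `w` bases immediately 3' of `end` (`right`),
#' on the reference strand, uppercased, truncated at contig edges. For a
#' deletion spanning `start..end` the windows lie outside the deleted
#' interval; for an insertion (`start == end` at the insertion point) the
#' left window ends at `start` and the right window begins at `start + 1`.
#' Runs never span the variant site itself: the two windows are kept
#' separate downstream.
#'
#' @param genome A `DNAStringSet`, a named character vector of contig
#'   sequences, or a FASTA path. Contig names must match the `chrom`
#'   values (an alias map may be applied with `chrom_alias`).
#' @param sites Data frame with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [parse_variant_key()]; a `key` column is carried
#'   through if present.
#' @param w Window size in bases per side (default 50).
#' @param chrom_alias Optional named character vector mapping MAF `chrom`
#'   values to contig names (e.g. `c("1" = "chr1")`).
#' @return Data frame of class `flank_context` with columns `key`,
#'   `chrom`, `start`, `end`, `left`, `right`; attribute `w` records the
#'   window size.
#' @export
extract_flanks <- function(genome, sites, w = 50L, chrom_alias = NULL) {
  genome <- .as_genome(genome)
  w <- as.integer(w)
  stopifnot(w >= 1L, all(c("chrom", "start", "end") %in% names(sites)))
  chrom <- as.character(sites$chrom)
  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- chrom_alias[chrom[hit]]
  }
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing) > 0L) {
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "))
  }
  if (any(sites$start < 1L)) stop("variant start < 1")
  clen <- stats::setNames(Biostrings::width(genome), names(genome))[chrom]
  if (any(sites$end > clen)) stop("variant end beyond contig length")
  seqs <- as.character(genome)[chrom]
  l_from <- pmax(1L, sites$start - w)
  left <- toupper(substring(seqs, l_from, sites$start - 1L))
  r_to <- pmin(clen, sites$end + w)
  right <- toupper(substring(seqs, sites$end + 1L, r_to))
  out <- data.frame(
    key = if ("key" %in% names(sites)) sites$key else
      paste0(sites$chrom, ":", sites$start),
    chrom = sites$chrom, start = sites$start, end = sites$end,
    left = left, right = right, stringsAsFactors = FALSE
  )
  attr(out, "w") <- w
  class(out) <- c("flank_context", class(out))
  out
}

#' GC fraction of flanking windows
#'
#' (#G + #C) / (#A + #C + #G + #T) over the concatenated left and right
#' windows; `N` bases are excluded from both numerator and denominator.
#' All-N (or empty) contexts return `NA` and should be excluded from
#' downstream comparisons.
#'
#' @param contexts A `flank_context` data frame from [extract_flanks()].
#' @return Numeric vector in \[0, 1\] (or `NA`), one value per context.
#' @export
gc_fraction <- function(contexts) {
  seqs <- paste0(contexts$left, contexts$right)
  counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(
    ifelse(seqs == "", "N", seqs)), c("A", "C", "G", "T"))
  tot <- rowSums(counts)
  ifelse(tot == 0, NA_real_, (counts[, "C"] + counts[, "G"]) / tot)
}

# max run length of base `base` in one sequence; N breaks runs.
.max_run_one <- function(chars, base) {
  if (length(chars) == 0L) return(0L)
  r <- rle(chars)
  hit <- r$values == base
  if (!any(hit)) 0L else max(r$lengths[hit])
}

#' Per-nucleotide maximum homopolymer runs in the flanks
#'
#' For each context and each nucleotide, the maximum length of a stretch
#' of identical bases within the left window and within the right window
#' (scanned separately, so runs never span the variant site). `N` breaks
#' runs.
#'
#' @param contexts A `flank_context` data frame.
#' @return Data frame with `key`, `max_run_A`, `max_run_C`, `max_run_G`,
#'   `max_run_T`, `overall_max`.
#' @export
homopolymer_profile <- function(contexts) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(contexts)
  m <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
  lchars <- strsplit(contexts$left, "", fixed = TRUE)
  rchars <- strsplit(contexts$right, "", fixed = TRUE)
  for (i in seq_len(n)) {
    for (b in bases) {
      m[i, b] <- max(.max_run_one(lchars[[i]], b),
                     .max_run_one(rchars[[i]], b))
    }
  }
  data.frame(
    key = contexts$key,
    max_run_A = m[, "A"], max_run_C = m[, "C"],
    max_run_G = m[, "G"], max_run_T = m[, "T"],
    overall_max = apply(m, 1L, max),
    stringsAsFactors = FALSE
  )
}

#' @export
`[.flank_context` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "w") <- attr(x, "w")
    class(out) <- unique(c("flank_context", class(out)))
  }
  out
}

# Trim a context set extracted at window W down to window w <= W.
.trim_contexts <- function(contexts, w) {
  W <- attr(contexts, "w")
  if (!is.null(W) && w > W) {
    stop("requested window ", w, " exceeds extraction window ", W)
  }
  out <- contexts
  out$left <- substring(out$left, pmax(1L, nchar(out$left) - w + 1L),
                     nchar(out$left))
  out$right <- substring(out$right, 1L, w)
  attr(out, "w") <- w
  out
}

#' Fraction of contexts with a long homopolymer run
#'
#' The fraction of contexts whose maximum run (over the four nucleotides,
#' within windows trimmed to `w` bases per side) is strictly greater than
#' `run_threshold`. Trimming keeps the bases nearest the variant, so a run
#' farther than `w` bases away is not counted.
#'
#' @param contexts A `flank_context` data frame extracted at a window of
#'   at least `w`.
#' @param run_threshold Run length that must be exceeded (default 5).
#' @param w Window size per side to evaluate (default: the extraction
#'   window).
#' @return Fraction in \[0, 1\].
#' @export
long_run_fraction <- function(contexts, run_threshold = 5L, w = NULL) {
  if (nrow(contexts) == 0L) stop("no contexts supplied")
  stopifnot(run_threshold >= 0L)
  if (is.null(w)) w <- attr(contexts, "w")
  prof <- homopolymer_profile(.trim_contexts(contexts, w))
  mean(prof$overall_max > run_threshold)
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-sided t-test with pooled variance. When the pooled variance is zero
#' the statistic is degenerate: `p = 1` if the means are equal, otherwise
#' `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
two_sample_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                p = if (eq) 1 else 0, df = nx + ny - 2, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Two-sided rank-shift (Mann-Whitney U) test
#'
#' Wilcoxon rank-sum test for a location shift between two samples: exact
#' enumeration when `length(x) * length(y) <= 400` and there are no ties,
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return Two-sided P-value.
#' @export
rank_shift_test <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  exact <- length(x) * length(y) <= 400 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Export per-variant context features as TSV
#'
#' @param contexts A `flank_context` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_context_features <- function(contexts, path) {
  out <- cbind(homopolymer_profile(contexts), gc = gc_fraction(contexts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
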