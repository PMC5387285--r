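# Position frequency matrices, information content, IUPAC consensus, and
# exhaustive k-mer enrichment.

.iupac_codes <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

#' Window sequences for motif analysis
#'
#' Concatenates each context's flanks into one aligned window, optionally
#' with the variant's reference base in the middle. Contexts of minus
#' strand genes may be reverse-complemented first (via `revcomp`) so that
#' transcript-oriented motifs such as the splice-acceptor `AG` align.
#'
#' @param contexts A `flank_context` data frame with full-length flanks
#'   (no contig-edge truncation).
#' @param genome Genome accessor (needed only when
#'   `include_variant_column = TRUE`, to fetch the reference base).
#' @param include_variant_column Include the reference base at the variant
#'   position as the central column (default `TRUE`).
#' @param revcomp Logical vector (recycled) marking contexts to
#'   reverse-complement (default none).
#' @return Character vector of equal-length window sequences.
#' @export
context_windows <- function(contexts, genome = NULL,
                            include_variant_column = TRUE, revcomp = FALSE) {
  w <- attr(contexts, "w")
  if (any(nchar(contexts$left) != w) || any(nchar(contexts$right) != w)) {
    stop("contexts are truncated at contig edges; motif windows need ",
         "full-length flanks")
  }
  if (include_variant_column) {
    if (is.null(genome)) stop("genome required for the variant column")
    g <- .as_genome(genome)
    seqs <- as.character(g)[contexts$chrom]
    centre <- toupper(substring(seqs, contexts$start, contexts$end))
    win <- paste0(contexts$left, centre, contexts$right)
    if (length(unique(nchar(win))) != 1L) {
      stop("variant alleles of mixed length; use ",
           "include_variant_column = FALSE")
    }
  } else {
    win <- paste0(contexts$left, contexts$right)
  }
  rc <- rep_len(revcomp, length(win))
  if (any(rc)) {
    win[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(win[rc])))
  }
  win
}

#' Build a position frequency matrix
#'
#' Per-position nucleotide counts over aligned equal-length sequences.
#' `N` bases are excluded, so column sums equal the number of sequences
#' minus the per-column `N` count.
#'
#' @param windows Character vector of equal-length sequences (e.g. from
#'   [context_windows()]).
#' @param positions Optional position labels (defaults to
#'   `-w..-1, 0, 1..w` when the length is odd, `-w..-1, 1..w` when even).
#' @return List of class `pfm`: `counts` (4 x P integer matrix, rows
#'   A/C/G/T), `positions`, `n_seqs`.
#' @export
build_pfm <- function(windows, positions = NULL) {
  if (length(windows) == 0L) stop("no sequences")
  L <- unique(nchar(windows))
  if (length(L) != 1L) stop("sequences have mixed window sizes")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  counts <- matrix(0L, 4L, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in c("A", "C", "G", "T")) {
    if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
  }
  if (is.null(positions)) {
    positions <- if (L %% 2L == 1L) {
      seq.int(-(L - 1L) / 2L, (L - 1L) / 2L)
    } else {
      c(seq.int(-L / 2L, -1L), seq.int(1L, L / 2L))
    }
  }
  stopifnot(length(positions) == L)
  colnames(counts) <- positions
  structure(list(counts = counts, positions = positions,
                 n_seqs = length(windows)),
            class = "pfm")
}

#' Per-position information content in bits
#'
#' `IC(pos) = 2 + sum_n f_n log2 f_n` with `0 log 0 = 0`, optionally minus
#' the small-sample correction `e(n) = 3 / (2 ln(2) n)`, clipped at 0.
#' Columns with zero observations (all `N`) are `NA`.
#'
#' @param pfm A [build_pfm()] result.
#' @param small_sample_correction Apply the correction (default `FALSE`).
#' @return Numeric vector of bits per position, named by position.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  tot <- colSums(pfm$counts)
  ic <- vapply(seq_along(tot), function(j) {
    if (tot[j] == 0) return(NA_real_)
    f <- pfm$counts[, j] / tot[j]
    f <- f[f > 0]
    2 + sum(f * log2(f))
  }, numeric(1))
  if (small_sample_correction) {
    ic <- ic - ifelse(tot > 0, 3 / (2 * log(2) * tot), 0)
  }
  stats::setNames(pmax(ic, 0), pfm$positions)
}

#' IUPAC consensus string of a PFM
#'
#' Per position: the single base whose frequency reaches
#' `majority_threshold`; otherwise (when `degenerate = TRUE`) the smallest
#' IUPAC code covering all bases with frequency at least
#' `(1 - majority_threshold) / 3`; otherwise `N`.
#'
#' @param pfm A [build_pfm()] result.
#' @param majority_threshold Majority frequency in (0.5, 1\] (default 0.7).
#' @param degenerate Emit degenerate IUPAC codes (default `TRUE`).
#' @return Consensus string, one character per position.
#' @export
consensus_string <- function(pfm, majority_threshold = 0.7,
                             degenerate = TRUE) {
  stopifnot(inherits(pfm, "pfm"),
            majority_threshold > 0.5, majority_threshold <= 1)
  bases <- rownames(pfm$counts)
  out <- vapply(seq_along(pfm$positions), function(j) {
    tot <- sum(pfm$counts[, j])
    if (tot == 0) return("N")
    f <- pfm$counts[, j] / tot
    if (max(f) >= majority_threshold) return(bases[which.max(f)])
    if (!degenerate) return("N")
    memb <- bases[f >= (1 - majority_threshold) / 3]
    if (length(memb) == 0L) return("N")
    unname(.iupac_codes[paste(sort(memb), collapse = "")])
  }, character(1))
  paste(out, collapse = "")
}

#' Exhaustive k-mer enrichment between two sequence sets
#'
#' For every k-mer occurring in the foreground set, counts the sequences
#' containing it (presence/absence per sequence) in foreground and
#' background, and tests enrichment with a one-sided Fisher's exact test
#' (greater). Rows are BH-adjusted and sorted by P (ties by k-mer).
#'
#' @param fg,bg Non-empty character vectors of sequences.
#' @param k k-mer length, at most the shortest sequence length.
#' @return Data frame `kmer`, `fg_count`, `bg_count`, `p`, `q`, sorted by
#'   ascending `p`.
#' @export
kmer_enrichment <- function(fg, bg, k) {
  stopifnot(length(fg) > 0L, length(bg) > 0L, k >= 1L)
  if (k > min(nchar(c(fg, bg)))) stop("k exceeds the shortest sequence")
  kmers_of <- function(s) {
    n <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  fg_sets <- lapply(fg, kmers_of)
  all_kmers <- sort(unique(unlist(fg_sets)))
  all_kmers <- all_kmers[!grepl("[^ACGT]", all_kmers)]
  fg_count <- table(factor(unlist(fg_sets), levels = all_kmers))
  bg_sets <- lapply(bg, kmers_of)
  bg_count <- table(factor(unlist(bg_sets), levels = all_kmers))
  a <- as.integer(fg_count); b <- length(fg) - a
  cc <- as.integer(bg_count); d <- length(bg) - cc
  p <- fisher_exact_p(a, b, cc, d, alternative = "greater")
  out <- data.frame(kmer = all_kmers, fg_count = a, bg_count = cc,
                    p = p, q = bh_fdr(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$kmer), ]
  rownames(out) <- NULL
  out
}

#' Write a PFM as tab-separated counts
#'
#' One row per position, columns `position`, `A`, `C`, `G`, `T`.
#'
#' @param pfm A [build_pfm()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  out <- data.frame(position = pfm$positions, t(pfm$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a PFM in MEME minimal motif format
#'
#' @param pfm A [build_pfm()] result.
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfm, path, name = "motif1") {
  tot <- colSums(pfm$counts)
  probs <- sweep(pfm$counts, 2L, pmax(tot, 1L), "/")
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
            ncol(probs), pfm$n_seqs),
    apply(probs, 2L, function(col) paste(sprintf("%.6f", col), collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}
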