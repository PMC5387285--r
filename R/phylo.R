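# Binary mutation profiles, Hamming distances, Neighbor-Joining, and the
# nearest-neighbor batch clustering score.

#' Binary mutation profiles
#'
#' Sample-by-variant presence/absence matrix: entry 1 when the sample
#' carries the variant site.
#'
#' @param dataset A [maf_dataset()].
#' @param keys Ordered character vector of variant keys (non-empty);
#'   defaults to all unique keys of the dataset.
#' @return Integer 0/1 matrix, rows = samples, columns = keys.
#' @export
binary_profiles <- function(dataset, keys = NULL) {
  stopifnot(inherits(dataset, "maf_dataset"))
  if (is.null(keys)) keys <- unique(variant_key(dataset))
  if (length(keys) == 0L) stop("empty key list")
  inc <- unique(data.frame(key = variant_key(dataset),
                           sample = dataset$variants$sample_barcode,
                           stringsAsFactors = FALSE))
  inc <- inc[inc$key %in% keys, , drop = FALSE]
  m <- matrix(0L, length(dataset$samples), length(keys),
              dimnames = list(dataset$samples, keys))
  if (nrow(inc) > 0L) {
    m[cbind(match(inc$sample, dataset$samples), match(inc$key, keys))] <- 1L
  }
  m
}

#' Hamming distance matrix between binary profiles
#'
#' `d(i, j)` is the number of variant columns on which samples `i` and `j`
#' differ, optionally divided by the number of columns.
#'
#' @param m 0/1 matrix (rows = samples).
#' @param normalize Divide by the column count (default `FALSE`).
#' @return Symmetric numeric matrix with zero diagonal, dimnames from the
#'   row names of `m`.
#' @export
hamming_distances <- function(m, normalize = FALSE) {
  stopifnot(nrow(m) >= 2L)
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  k <- rowSums(m)
  d <- outer(k, k, "+") - 2 * tcrossprod(m)
  d[d < 0] <- 0  # guard against floating-point dust
  diag(d) <- 0
  if (normalize) d <- d / ncol(m)
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` (`R` = row sums), with the
#' standard branch-length formulas. Ties are broken deterministically by
#' label order, so the tree is reproducible. A negative branch length is
#' clipped to 0 with the deficit transferred to its sister edge, keeping
#' the path length of the joined pair intact.
#'
#' @param d Symmetric distance matrix with at least 3 labelled rows.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n < 3L) stop("Neighbor-Joining needs at least 3 taxa")
  labels <- rownames(d)
  frag <- labels  # newick fragment per active cluster
  dm <- as.matrix(d)
  fmt <- function(x) sprintf("%.17g", x)
  while (length(frag) > 3L) {
    m <- nrow(dm)
    R <- rowSums(dm)
    Q <- (m - 2) * dm - outer(R, R, "+")
    diag(Q) <- Inf
    # deterministic arg-min: smallest Q, ties by (row, col) index where the
    # active clusters are kept in original join order
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- idx[1L, 1L]; j <- idx[1L, 2L]
    li <- dm[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    du <- (dm[i, ] + dm[j, ] - dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    dm2 <- rbind(cbind(dm[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    dm <- dm2
  }
  # closed form for the final three clusters
  la <- (dm[1, 2] + dm[1, 3] - dm[2, 3]) / 2
  lb <- (dm[1, 2] + dm[2, 3] - dm[1, 3]) / 2
  lc <- (dm[1, 3] + dm[2, 3] - dm[1, 2]) / 2
  l3 <- pmax(c(la, lb, lc), 0)
  newick <- paste0("(", frag[1], ":", fmt(l3[1]), ",",
                   frag[2], ":", fmt(l3[2]), ",",
                   frag[3], ":", fmt(l3[3]), ");")
  ape::read.tree(text = newick)
}

#' Nearest-neighbor batch clustering score
#'
#' The fraction of samples whose nearest neighbor (excluding self; ties
#' broken by lexicographic sample label) carries the same batch label.
#' High scores mean samples cluster by batch.
#'
#' @param d Symmetric distance matrix with labelled rows.
#' @param labels Named character vector: sample -> batch value, covering
#'   all rows of `d`; at least two distinct values must be present.
#' @return Score in \[0, 1\].
#' @export
batch_clustering_score <- function(d, labels) {
  samples <- rownames(d)
  stopifnot(!is.null(samples), all(samples %in% names(labels)))
  lab <- labels[samples]
  if (length(unique(lab)) < 2L) {
    stop("batch clustering score is undefined with a single batch label")
  }
  ord <- order(samples)  # lexicographic preference among tied neighbors
  hits <- vapply(seq_along(samples), function(i) {
    dd <- d[i, ord]
    dd[ord == i] <- Inf
    nn <- ord[which.min(dd)]
    lab[nn] == lab[i]
  }, logical(1))
  mean(hits)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d Symmetric distance matrix with labelled rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], sprintf("%.6f", d[i, ])),
                     collapse = "  "), con)
  }
  invisible(path)
}
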