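# MAF reading/writing, TCGA barcode parsing, dataset-level QC.

# Canonical internal column names and the standard MAF header synonyms we
# accept (matched case-insensitively).
.maf_columns <- c(
  "gene_symbol", "chrom", "start", "end", "ref_allele", "alt_allele",
  "variant_type", "variant_classification", "sample_barcode"
)

.maf_synonyms <- list(
  gene_symbol            = c("gene_symbol", "hugo_symbol", "gene"),
  chrom                  = c("chrom", "chromosome", "chr"),
  start                  = c("start", "start_position", "start_pos"),
  end                    = c("end", "end_position", "end_pos"),
  ref_allele             = c("ref_allele", "reference_allele", "ref"),
  alt_allele             = c("alt_allele", "tumor_seq_allele2", "tumor_seq_allele",
                             "alt"),
  variant_type           = c("variant_type"),
  variant_classification = c("variant_classification"),
  sample_barcode         = c("sample_barcode", "tumor_sample_barcode")
)

# Standard TCGA-style header used on write so files round-trip through
# third-party MAF readers.
.maf_write_header <- c(
  gene_symbol            = "Hugo_Symbol",
  chrom                  = "Chromosome",
  start                  = "Start_Position",
  end                    = "End_Position",
  ref_allele             = "Reference_Allele",
  alt_allele             = "Tumor_Seq_Allele2",
  variant_type           = "Variant_Type",
  variant_classification = "Variant_Classification",
  sample_barcode         = "Tumor_Sample_Barcode"
)

.variant_classifications <- c(
  "missense", "nonsense", "silent", "splice_site", "frameshift_ins",
  "frameshift_del", "inframe_ins", "inframe_del", "stop_loss", "other"
)

#' Construct a MAF dataset
#'
#' A `maf_dataset` bundles a variant table (one row per called variant per
#' tumor sample) with the dataset name and cancer type. Sample identity is
#' the full barcode string, because batch variables (plate, analyte) live in
#' the barcode tail, not in the participant prefix.
#'
#' @param variants Data frame with at least the nine canonical columns
#'   (`gene_symbol`, `chrom`, `start`, `end`, `ref_allele`, `alt_allele`,
#'   `variant_type`, `variant_classification`, `sample_barcode`). Extra
#'   columns are preserved.
#' @param name Dataset name (used in reports and cross-dataset tables).
#' @param cancer_type Free-text cancer type label.
#' @return An object of class `maf_dataset` with elements `name`,
#'   `cancer_type`, `variants` (data frame) and `samples` (unique barcodes,
#'   in order of first appearance).
#' @export
maf_dataset <- function(variants, name = "maf", cancer_type = NA_character_) {
  stopifnot(is.data.frame(variants))
  missing <- setdiff(.maf_columns, names(variants))
  if (length(missing) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  variants$start <- as.integer(variants$start)
  variants$end <- as.integer(variants$end)
  bad <- which(variants$start > variants$end)
  if (length(bad) > 0L) {
    stop("start > end at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(variants$variant_type %in% c("SNP", "INS", "DEL"))) {
    stop("variant_type must be one of SNP, INS, DEL")
  }
  # Barcode parse errors are reported with the offending row numbers.
  parse_barcode(variants$sample_barcode)
  structure(
    list(
      name = name,
      cancer_type = cancer_type,
      variants = variants,
      samples = unique(variants$sample_barcode)
    ),
    class = "maf_dataset"
  )
}

#' @export
print.maf_dataset <- function(x, ...) {
  cat(sprintf(
    "maf_dataset '%s' (%s): %d variant records, %d samples, %d indel records\n",
    x$name, ifelse(is.na(x$cancer_type), "?", x$cancer_type),
    nrow(x$variants), length(x$samples),
    sum(x$variants$variant_type %in% c("INS", "DEL"))
  ))
  invisible(x)
}

.match_maf_header <- function(header) {
  lower <- tolower(header)
  idx <- vapply(.maf_synonyms, function(syn) {
    hit <- which(lower %in% syn)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing) > 0L) {
    stop("MAF header is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  idx
}

#' Read a MAF file
#'
#' Reads a tab-separated MAF-dialect file. Both the standard TCGA header
#' (`Hugo_Symbol`, `Tumor_Sample_Barcode`, ...) and the minimal lower-case
#' dialect written by [write_maf()] are accepted via a synonym map; matching
#' is case-insensitive. Lines starting with `#` are treated as comments.
#' Columns beyond the nine required ones are preserved.
#'
#' @param path Path to a tab-separated MAF file.
#' @param name Dataset name; defaults to the file name without extension.
#' @param cancer_type Optional cancer-type label.
#' @return A [maf_dataset()].
#' @export
read_maf <- function(path, name = NULL, cancer_type = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  idx <- .match_maf_header(names(tab))
  extra <- setdiff(seq_along(tab), idx)
  out <- tab[, idx, drop = FALSE]
  names(out) <- names(idx)
  if (length(extra) > 0L) out <- cbind(out, tab[, extra, drop = FALSE])
  maf_dataset(out, name = name, cancer_type = cancer_type)
}

#' Write a MAF dataset as tab-separated text
#'
#' Writes the standard TCGA-style header; extra columns follow the nine
#' canonical ones. The output re-reads with [read_maf()] field-for-field.
#'
#' @param dataset A [maf_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(dataset, path) {
  stopifnot(inherits(dataset, "maf_dataset"))
  tab <- dataset$variants
  core <- tab[, .maf_columns, drop = FALSE]
  names(core) <- unname(.maf_write_header[.maf_columns])
  extra <- tab[, setdiff(names(tab), .maf_columns), drop = FALSE]
  out <- if (ncol(extra) > 0L) cbind(core, extra) else core
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse TCGA-style sample barcodes
#'
#' A TCGA barcode is a dash-delimited string whose positional fields encode
#' the project, tissue source site (TSS), participant, sample/vial,
#' portion/analyte, plate, and sequencing center, e.g.
#' `TCGA-AA-1234-01A-01D-0886-08`. Fields beyond the seventh are ignored.
#'
#' @param x Character vector of barcodes, each with at least 7 fields.
#' @return Data frame with one row per barcode: `barcode`, `project`,
#'   `tss_id`, `participant`, `sample_vial`, `portion_analyte`, `plate_id`,
#'   `center_id`, and `participant_id` (the first three fields re-joined).
#' @examples
#' parse_barcode("TCGA-AA-1234-01A-01D-0886-08")
#' @export
parse_barcode <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 7L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "barcode with fewer than 7 dash-delimited fields at position(s) %s (e.g. '%s')",
      paste(utils::head(bad, 5L), collapse = ", "), x[bad[1L]]
    ))
  }
  m <- t(vapply(parts, function(p) p[1:7], character(7)))
  data.frame(
    barcode = x,
    project = m[, 1L], tss_id = m[, 2L], participant = m[, 3L],
    sample_vial = m[, 4L], portion_analyte = m[, 5L],
    plate_id = m[, 6L], center_id = m[, 7L],
    participant_id = paste(m[, 1L], m[, 2L], m[, 3L], sep = "-"),
    stringsAsFactors = FALSE
  )
}

#' Dataset-level quality control
#'
#' Drops datasets that are unusable for batch-bias testing: an extremely
#' high indel load (more than `max_indels` indel records, indicating a
#' pathological caller), no indels at all, or fewer than `min_samples`
#' unique tumor barcodes. The sample count is over unique tumor barcodes,
#' not participants.
#'
#' @param datasets List of [maf_dataset()] objects.
#' @param max_indels Maximum allowed indel record count (default 500000).
#' @param min_samples Minimum sample count; datasets with fewer than this
#'   many samples are dropped (default 100, i.e. 100 samples is kept).
#' @return List with `kept` (list of datasets) and `dropped` (data frame
#'   with columns `name` and `reason`; zero rows when nothing is dropped).
#' @export
qc_filter_datasets <- function(datasets, max_indels = 500000L,
                               min_samples = 100L) {
  stopifnot(is.list(datasets))
  reasons <- vapply(datasets, function(d) {
    n_indel <- sum(d$variants$variant_type %in% c("INS", "DEL"))
    if (n_indel > max_indels) {
      sprintf("extremely high frequency of indels (>%d)", max_indels)
    } else if (n_indel == 0L) {
      "no indels"
    } else if (length(d$samples) < min_samples) {
      sprintf("sample sizes less than %d", min_samples)
    } else {
      NA_character_
    }
  }, character(1))
  keep <- is.na(reasons)
  dropped <- data.frame(
    name = vapply(datasets[!keep], `[[`, character(1), "name"),
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  list(kept = datasets[keep], dropped = dropped)
}

#' Variant site keys
#'
#' The identity of a genomic change, used for sample-level counting and
#' cross-dataset matching: `chrom:start:ref>alt`. Equal keys denote the same
#' substitution or indel regardless of dataset or carrier.
#'
#' @param x A `maf_dataset` or a variant data frame.
#' @return Character vector of keys, one per variant record.
#' @export
variant_key <- function(x) {
  v <- if (inherits(x, "maf_dataset")) x$variants else x
  paste0(v$chrom, ":", v$start, ":", v$ref_allele, ">", v$alt_allele)
}

#' Decompose variant keys into site coordinates
#'
#' @param keys Character vector of `chrom:start:ref>alt` keys.
#' @return Data frame with `key`, `chrom`, `start`, `end`, `ref_allele`,
#'   `alt_allele`. For a pure insertion (`ref == "-"`), `end == start`; for
#'   SNPs and deletions, `end = start + nchar(ref) - 1`.
#' @export
parse_variant_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+):([^>]+)>(.+)$", keys))
  bad <- which(lengths(m) != 5L)
  if (length(bad) > 0L) stop("malformed variant key: ", keys[bad[1L]])
  m <- do.call(rbind, m)
  ref <- m[, 4L]
  start <- as.integer(m[, 3L])
  end <- ifelse(ref == "-", start, start + nchar(ref) - 1L)
  data.frame(
    key = keys, chrom = m[, 2L], start = start, end = as.integer(end),
    ref_allele = ref, alt_allele = m[, 5L], stringsAsFactors = FALSE
  )
}
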