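#' Filter reads by mean Phred quality
#'
#' Retains reads whose mean Phred quality is greater than or equal to
#' `min_q` (reads strictly below the threshold are discarded, so a read at
#' exactly Q = 7 is kept under the default). Order is preserved and the
#' operation is idempotent.
#'
#' @param reads Read table (see [simulate_reads()]).
#' @param min_q Phred threshold, >= 0. Default 7, the usual pass/fail
#'   cutoff for Nanopore basecalling.
#' @return The retained rows, with attributes `n_pass` (count) and
#'   `pass_fraction` (count / input size; `NaN` on empty input).
#' @export
quality_filter <- function(reads, min_q = 7) {
  if (!is.numeric(min_q) || min_q < 0)
    stop("`min_q` must be >= 0", call. = FALSE)
  keep <- reads$mean_q >= min_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pass") <- sum(keep)
  attr(out, "pass_fraction") <- if (nrow(reads)) sum(keep) / nrow(reads) else NaN
  out
}

#' Split reads by barcode
#'
#' Partition a read table into one group per barcode label; reads without
#' a barcode go into a separate `"unclassified"` group. Group sizes always
#' sum to the input size. Barcode trimming and mismatch-tolerant matching
#' are out of scope: the barcode field is taken as exact.
#'
#' @param reads Read table.
#' @return A named list of read tables, one per barcode (sorted by label),
#'   plus `"unclassified"` when unbarcoded reads are present.
#' @export
demultiplex <- function(reads) {
  bc <- reads$barcode
  label <- ifelse(is.na(bc), "unclassified", bc)
  groups <- split(reads, factor(label, levels = sort(unique(label))))
  lapply(groups, function(g) { rownames(g) <- NULL; g })
}

#' Count reads per gene
#'
#' Builds a one-column count matrix over the full catalog: the count of a
#' gene is the number of reads assigned to it; unmapped reads are excluded
#' and genes with no reads get 0, so the column sum equals the number of
#' mapped reads.
#'
#' @param reads Read table (normally quality-filtered first).
#' @param catalog Gene catalog; defines the gene axis and its order.
#' @param sample_label Column name for the resulting matrix.
#' @return Integer matrix (genes x 1) with `rownames` = `gene_id`.
#' @export
count_reads <- function(reads, catalog, sample_label = "sample1") {
  mapped <- reads$gene_id[!is.na(reads$gene_id)]
  unknown <- setdiff(unique(mapped), catalog$gene_id)
  if (length(unknown))
    stop("reads reference gene(s) absent from catalog: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) " ...", call. = FALSE)
  counts <- tabulate(factor(mapped, levels = catalog$gene_id),
                     nbins = nrow(catalog))
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(catalog$gene_id, sample_label))
  m
}

#' Parse a featureCounts-style count table
#'
#' Expects the featureCounts TSV dialect: an optional leading comment line
#' beginning with `#`, then a header `Geneid, Chr, Start, End, Strand,
#' Length` followed by one column per sample. The annotation columns are
#' discarded; counts must be non-negative integers and gene ids unique.
#'
#' @param path Path to the TSV file.
#' @return Integer count matrix (genes x samples).
#' @export
read_featurecounts_table <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  x <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  anno <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  if (ncol(x) < length(anno) + 1L || !identical(colnames(x)[1:6], anno))
    stop("missing featureCounts header (Geneid, Chr, Start, End, Strand, ",
         "Length, <samples>) in ", path, call. = FALSE)
  if (anyDuplicated(x$Geneid))
    stop("duplicate Geneid values in ", path, call. = FALSE)
  samples <- colnames(x)[-(1:6)]
  vals <- as.matrix(x[, samples, drop = FALSE])
  if (!all(grepl("^[0-9]+$", vals)))
    stop("non-integer or negative count values in ", path, call. = FALSE)
  m <- matrix(as.integer(vals), nrow = nrow(x),
              dimnames = list(x$Geneid, samples))
  m
}

#' Per-barcode sequencing summary
#'
#' Mirrors the per-sample statistics reported for a multiplexed run: one
#' row per barcode with the total read count, mapped read count and the
#' number of expressed genes (read count strictly greater than
#' `threshold`). Derived across-barcode statistics are computed by
#' [barcode_stats()].
#'
#' @param groups Demultiplexed read groups from [demultiplex()].
#' @param catalog Gene catalog.
#' @param threshold Expression threshold on raw counts (default 3; a gene
#'   is expressed when count > 3).
#' @return A `data.frame` with columns `barcode`, `total_reads`,
#'   `mapped_reads`, `n_genes`.
#' @export
barcode_summary <- function(groups, catalog, threshold = 3) {
  if (!length(groups)) stop("no barcode groups supplied", call. = FALSE)
  rows <- lapply(names(groups), function(b) {
    g <- groups[[b]]
    counts <- count_reads(g, catalog, b)
    data.frame(
      barcode = b,
      total_reads = nrow(g),
      mapped_reads = sum(!is.na(g$gene_id)),
      n_genes = sum(counts > threshold),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Across-barcode statistics for a multiplex summary
#'
#' Computes the across-barcode mean of total reads, the summed total, the
#' minimum expressed-gene count and the coefficient of variation (CV) of
#' the gene numbers. The CV uses the sample standard deviation (n - 1
#' denominator), as a percentage of the mean; it is `NA` for a single
#' barcode.
#'
#' @param summary_table A table with columns `total_reads` and `n_genes`,
#'   e.g. from [barcode_summary()] or read from a published run summary.
#' @return A list with `mean_total_reads`, `sum_total_reads`,
#'   `min_genes`, `mean_genes`, `cv_genes_percent`.
#' @export
barcode_stats <- function(summary_table) {
  stopifnot(all(c("total_reads", "n_genes") %in% colnames(summary_table)))
  if (!nrow(summary_table)) stop("empty summary table", call. = FALSE)
  g <- summary_table$n_genes
  cv <- if (length(g) > 1L) 100 * stats::sd(g) / mean(g) else NA_real_
  list(
    mean_total_reads = mean(summary_table$total_reads),
    sum_total_reads = sum(summary_table$total_reads),
    min_genes = min(g),
    mean_genes = mean(g),
    cv_genes_percent = cv
  )
}
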