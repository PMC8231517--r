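#' Counts per million
#'
#' Scales each sample (column) so counts sum to one million:
#' `CPM_g = count_g / sum(counts) * 1e6`. Gene length plays no role: for
#' long-read cDNA counting each read is one molecule.
#'
#' @param counts Non-negative count matrix (genes x samples) or a single
#'   column.
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
cpm <- function(counts) {
  counts <- as_count_matrix(counts)
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "), call. = FALSE)
  sweep(counts, 2, libsize, "/") * 1e6
}

#' Expressed-gene detection mask
#'
#' A gene is deemed expressed in a sample when its raw read count is
#' strictly greater than `threshold` (default 3, i.e. count >= 4).
#'
#' @param counts Count matrix.
#' @param threshold Count threshold (strict inequality).
#' @return Logical matrix of the same shape.
#' @export
detect_expressed <- function(counts, threshold = 3) {
  counts <- as_count_matrix(counts)
  counts > threshold
}

#' log2(CPM) expression matrix for expressed genes
#'
#' Computes `log2(CPM)` and masks out non-expressed entries (count <=
#' `threshold`) as `NA`. No pseudocount is added: expressed genes have
#' count >= 4, so CPM is always positive.
#'
#' @inheritParams detect_expressed
#' @return Numeric matrix of log2(CPM) with `NA` where not expressed.
#' @export
log2cpm <- function(counts, threshold = 3) {
  counts <- as_count_matrix(counts)
  v <- log2(cpm(counts))
  v[!detect_expressed(counts, threshold)] <- NA_real_
  v
}

#' Expression quartile classes from a reference column
#'
#' Detected coding and non-coding genes are ranked separately by their
#' reference log2(CPM) and split at the 25/50/75 rank percentiles into Q1
#' (low) .. Q4 (high) expression classes; within each coding class the
#' class sizes differ by at most one. Ties are broken by a stable sort on
#' (value, gene_id) so the classification is reproducible.
#'
#' The classes are meant to be computed once on the reference (full)
#' dataset and then held fixed across subsets.
#'
#' With `by_class = FALSE` the quartile boundaries are instead taken from
#' the pooled detected-gene distribution (coding and non-coding ranked
#' together), which is the variant to use when asking whether one biotype
#' is over-represented in a given expression class.
#'
#' @param expr_col Named numeric vector of reference log2(CPM) values
#'   (`NA` = not expressed), names = gene ids.
#' @param catalog Gene catalog supplying `coding_class`.
#' @param by_class Rank coding and non-coding genes separately (default)
#'   or pooled.
#' @return A `data.frame` with columns `gene_id`, `coding_class`,
#'   `quartile` (`"Q1"`..`"Q4"`), one row per detected gene.
#' @export
quartile_classes <- function(expr_col, catalog, by_class = TRUE) {
  if (is.matrix(expr_col)) {
    stopifnot(ncol(expr_col) == 1)
    expr_col <- stats::setNames(expr_col[, 1], rownames(expr_col))
  }
  if (is.null(names(expr_col)))
    stop("`expr_col` must be named by gene_id", call. = FALSE)
  detected <- names(expr_col)[!is.na(expr_col)]
  if (!length(detected)) stop("no detected genes in `expr_col`", call. = FALSE)
  cls <- stats::setNames(catalog$coding_class, catalog$gene_id)[detected]
  if (anyNA(cls))
    stop("detected gene(s) absent from catalog", call. = FALSE)
  grouping <- if (by_class) cls else rep("all", length(detected))
  out <- lapply(split(detected, grouping), function(genes) {
    if (length(genes) < 4L)
      stop("fewer than 4 detected genes in a coding class; ",
           "cannot form quartiles", call. = FALSE)
    ord <- genes[order(expr_col[genes], genes)]
    q <- ceiling(seq_along(ord) * 4 / length(ord))
    data.frame(gene_id = ord,
               quartile = paste0("Q", q),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$coding_class <- unname(cls[res$gene_id])
  rownames(res) <- NULL
  res[, c("gene_id", "coding_class", "quartile")]
}

# coerce vector/matrix input to a validated integer-like matrix
as_count_matrix <- function(counts) {
  if (is.vector(counts)) {
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "sample1"))
  }
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix or vector", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  counts
}
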