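#' Pearson product-moment correlation with p-value
#'
#' Closed-form product-moment correlation plus the two-sided p-value from
#' the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) stop("zero variance in input", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Pair two expression columns for correlation
#'
#' Builds paired log2(CPM) vectors from two expression columns (`NA` =
#' not expressed). Mode `"intersection"` keeps genes expressed in both
#' samples; `"union-zero"` keeps genes expressed in either and imputes the
#' missing side as 0 (a log2(CPM) proxy flagged in the result).
#'
#' @param a,b Named numeric vectors (or one-column matrices) of log2(CPM).
#' @param mode `"intersection"` (default) or `"union-zero"`.
#' @return A list with vectors `x`, `y`, the gene ids used, the `mode`,
#'   and `imputed` (logical per gene, union-zero mode only).
#' @export
pair_expression <- function(a, b, mode = c("intersection", "union-zero")) {
  mode <- match.arg(mode)
  a <- as_expr_col(a)
  b <- as_expr_col(b)
  common <- intersect(names(a), names(b))
  a <- a[common]
  b <- b[common]
  if (mode == "intersection") {
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) stop("no genes expressed in both samples", call. = FALSE)
    list(x = unname(a[keep]), y = unname(b[keep]),
         gene_id = common[keep], mode = mode, imputed = NULL)
  } else {
    keep <- !is.na(a) | !is.na(b)
    if (!any(keep)) stop("no genes expressed in either sample", call. = FALSE)
    x <- a[keep]; y <- b[keep]
    imputed <- is.na(x) | is.na(y)
    x[is.na(x)] <- 0
    y[is.na(y)] <- 0
    list(x = unname(x), y = unname(y), gene_id = common[keep],
         mode = mode, imputed = unname(imputed))
  }
}

as_expr_col <- function(v) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 1)
    v <- stats::setNames(v[, 1], rownames(v))
  }
  if (is.null(names(v))) stop("expression column must be named by gene_id",
                              call. = FALSE)
  v
}

#' Delta-Ct values of a qPCR panel
#'
#' `dCt = Ct(target) - Ct(reference)`, per gene, order preserved. Lower
#' dCt means higher expression relative to the reference gene (typically
#' GAPDH).
#'
#' @param panel `data.frame` with columns `gene_id`, `ct_target`,
#'   `ct_reference`.
#' @return The panel with an added `dct` column.
#' @export
dct <- function(panel) {
  need <- c("gene_id", "ct_target", "ct_reference")
  if (!all(need %in% colnames(panel)))
    stop("panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyNA(panel$ct_reference)) stop("missing reference Ct", call. = FALSE)
  if (any(panel$ct_target <= 0) || any(panel$ct_reference <= 0))
    stop("Ct values must be positive", call. = FALSE)
  panel$dct <- panel$ct_target - panel$ct_reference
  panel
}

#' Concordance between sequencing expression and a qPCR panel
#'
#' Correlates log2(CPM) with dCt over the panel genes present in the
#' expression column. Because higher expression gives LOWER dCt the
#' natural sign of the correlation is negative; both the signed r and |r|
#' are reported, with |r| as the headline value.
#'
#' @param expr_col Named log2(CPM) vector (`NA` = not expressed).
#' @param panel qPCR panel (see [dct()]); `dct` computed if absent.
#' @return A list with `r_signed`, `r_abs`, `p_value`, `n_genes`,
#'   `genes_used`, `genes_excluded`.
#' @export
qpcr_concordance <- function(expr_col, panel) {
  expr_col <- as_expr_col(expr_col)
  if (!"dct" %in% colnames(panel)) panel <- dct(panel)
  present <- panel$gene_id %in% names(expr_col) &
    !is.na(expr_col[panel$gene_id])
  excluded <- panel$gene_id[!present]
  if (length(excluded))
    message(length(excluded), " panel gene(s) not expressed in the data: ",
            paste(excluded, collapse = ", "))
  used <- panel[present, , drop = FALSE]
  if (nrow(used) < 3)
    stop("fewer than 3 panel genes overlap the expression data", call. = FALSE)
  ct <- pearson(unname(expr_col[used$gene_id]), used$dct)
  list(r_signed = ct$r, r_abs = abs(ct$r), p_value = ct$p_value,
       n_genes = ct$n, genes_used = used$gene_id, genes_excluded = excluded)
}

#' Compare barcoded samples against an equal-size random subset
#'
#' For a multiplexed run, draws one random subset of the reference reads
#' whose size matches the mean per-barcode read count, quantifies it, and
#' correlates each barcode's log2(CPM) against the subset's over the
#' intersection of expressed genes. High correlations indicate that a
#' barcoded (shallower) sample quantifies expression as reliably as an
#' equally deep subset of a single-sample run.
#'
#' @param groups Demultiplexed read groups ([demultiplex()]); an
#'   `"unclassified"` group, if present, is ignored.
#' @param reference_reads Read table of the reference (single-sample) run,
#'   quality-filtered.
#' @param catalog Gene catalog.
#' @param threshold Expression threshold on raw counts.
#' @param seed Seed for the reference subset draw.
#' @return A list with `subset_size`, `subset_n_genes` and a `data.frame`
#'   `per_barcode` (`barcode`, `n_genes`, `n_common_genes`, `r`,
#'   `p_value`).
#' @export
multiplex_vs_subset <- function(groups, reference_reads, catalog,
                                threshold = 3, seed = 1L) {
  groups <- groups[setdiff(names(groups), "unclassified")]
  if (!length(groups)) stop("no barcode groups supplied", call. = FALSE)
  size <- round_half_up(mean(vapply(groups, nrow, numeric(1))))
  if (size > nrow(reference_reads))
    stop("reference has fewer reads than the mean barcode size", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(nrow(reference_reads), size))
  sub_counts <- count_reads(reference_reads[idx, , drop = FALSE],
                            catalog, "subset")
  sub_expr <- log2cpm(sub_counts, threshold)[, 1]
  rows <- lapply(names(groups), function(b) {
    bc_counts <- count_reads(groups[[b]], catalog, b)
    bc_expr <- log2cpm(bc_counts, threshold)[, 1]
    pair <- pair_expression(bc_expr, sub_expr, mode = "intersection")
    ct <- pearson(pair$x, pair$y)
    data.frame(barcode = b,
               n_genes = sum(!is.na(bc_expr)),
               n_common_genes = length(pair$gene_id),
               r = ct$r, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  list(subset_size = size,
       subset_n_genes = sum(!is.na(sub_expr)),
       per_barcode = do.call(rbind, rows))
}
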