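#' Specification of a replicated fractional subsampling design
#'
#' @param fractions Subset fractions, strictly in (0, 1]. Defaults to the
#'   usual depth ladder 90% down to 5%.
#' @param n_replicates Random replicates per fraction (default 10).
#' @param base_seed Integer; per-replicate seeds are derived
#'   deterministically as `base_seed + 10007 * fraction_index +
#'   replicate_index`, which is collision-free for the defaults.
#' @return A list of class `subset_spec`.
#' @export
subset_spec <- function(fractions = c(0.9, 0.8, 0.7, 0.6, 0.5,
                                      0.4, 0.3, 0.2, 0.1, 0.05),
                        n_replicates = 10L,
                        base_seed = 1L) {
  if (!length(fractions) || any(fractions <= 0) || any(fractions > 1))
    stop("fractions must lie strictly in (0, 1]", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  structure(list(fractions = as.numeric(fractions),
                 n_replicates = n_replicates,
                 base_seed = as.integer(base_seed)),
            class = "subset_spec")
}

replicate_seed <- function(spec, fraction_index, replicate_index) {
  spec$base_seed + 10007L * as.integer(fraction_index) +
    as.integer(replicate_index)
}

#' Subset size for a sampling fraction
#'
#' `round_half_up(fraction * total_reads)`: rounding is half away from
#' zero, the convention that exactly reproduces published subset sizes
#' (e.g. a 50% subset of 48,495,343 reads is 24,247,671.5, reported as
#' 24,247,672).
#'
#' @param total_reads Total read count.
#' @param fraction Sampling fraction in (0, 1].
#' @return Integer-valued subset size (as double to avoid 32-bit overflow
#'   on large libraries).
#' @export
subset_size <- function(total_reads, fraction) {
  if (any(fraction <= 0) || any(fraction > 1))
    stop("fraction must lie in (0, 1]", call. = FALSE)
  round_half_up(fraction * total_reads)
}

#' Replicated read-level subsampling
#'
#' For every (fraction, replicate) pair draws a uniform random subset of
#' exactly [subset_size()] reads without replacement, independently per
#' replicate from its derived seed, and recomputes the per-gene counts on
#' the subset. Sampling is over ALL supplied reads (quality-passed,
#' mapped or not), so the subset's total size scales exactly with the
#' fraction while its mapped count is random.
#'
#' @param reads Read table (normally quality-filtered).
#' @param spec A [subset_spec()].
#' @param catalog Gene catalog (defines the count axis).
#' @return A list of replicate records, each a list with `fraction`,
#'   `replicate`, `seed`, `counts` (named integer vector over the
#'   catalog), `n_total_reads`, `n_mapped_reads`.
#' @export
subsample <- function(reads, spec, catalog) {
  stopifnot(inherits(spec, "subset_spec"))
  n <- nrow(reads)
  if (!n) stop("`reads` is empty", call. = FALSE)
  # precompute the gene index once; tabulate per subset
  gene_idx <- match(reads$gene_id, catalog$gene_id)
  if (any(!is.na(reads$gene_id) & is.na(gene_idx)))
    stop("reads reference gene(s) absent from catalog", call. = FALSE)
  out <- list()
  for (fi in seq_along(spec$fractions)) {
    f <- spec$fractions[fi]
    size <- subset_size(n, f)
    if (size < 1) stop("subset size 0 for fraction ", f, call. = FALSE)
    for (r in seq_len(spec$n_replicates)) {
      seed <- replicate_seed(spec, fi, r)
      idx <- withr::with_seed(seed, sample.int(n, size))
      sub_idx <- gene_idx[idx]
      counts <- tabulate(sub_idx[!is.na(sub_idx)], nbins = nrow(catalog))
      out[[length(out) + 1L]] <- list(
        fraction = f,
        replicate = r,
        seed = seed,
        counts = stats::setNames(as.integer(counts), catalog$gene_id),
        n_total_reads = size,
        n_mapped_reads = sum(counts)
      )
    }
  }
  out
}

# multivariate hypergeometric draw by sequential conditioning
rmvhyper <- function(counts, size) {
  k <- as.numeric(counts)
  total <- sum(k)
  if (size > total) stop("subset larger than library", call. = FALSE)
  out <- numeric(length(k))
  remaining <- total
  n <- size
  for (i in seq_along(k)) {
    if (n == 0) break
    remaining <- remaining - k[i]
    x <- stats::rhyper(1, k[i], remaining, n)
    out[i] <- x
    n <- n - x
  }
  as.integer(out)
}

#' Replicated count-level subsampling
#'
#' Count-level equivalent of [subsample()] for users who only have a count
#' table: each replicate is a multivariate hypergeometric draw of
#' [subset_size()] reads across genes, which matches the distribution of
#' read-level subsampling of the same library.
#'
#' @param counts Named non-negative integer vector (or one-column matrix)
#'   of per-gene counts.
#' @param spec A [subset_spec()].
#' @return Same structure as [subsample()]; here every sampled read is
#'   mapped, so `n_mapped_reads == n_total_reads`.
#' @export
subsample_counts <- function(counts, spec) {
  stopifnot(inherits(spec, "subset_spec"))
  if (is.matrix(counts)) {
    stopifnot(ncol(counts) == 1)
    counts <- stats::setNames(counts[, 1], rownames(counts))
  }
  total <- sum(counts)
  out <- list()
  for (fi in seq_along(spec$fractions)) {
    f <- spec$fractions[fi]
    size <- subset_size(total, f)
    if (size < 1) stop("subset size 0 for fraction ", f, call. = FALSE)
    if (size > total) stop("subset larger than library", call. = FALSE)
    for (r in seq_len(spec$n_replicates)) {
      seed <- replicate_seed(spec, fi, r)
      sub <- withr::with_seed(seed, rmvhyper(counts, size))
      out[[length(out) + 1L]] <- list(
        fraction = f,
        replicate = r,
        seed = seed,
        counts = stats::setNames(sub, names(counts)),
        n_total_reads = size,
        n_mapped_reads = sum(sub)
      )
    }
  }
  out
}

#' Gene-detection saturation curve
#'
#' Summarizes a replicated subsampling run into a per-fraction table of
#' mean detected genes (total, coding, non-coding), the coefficient of
#' variation of the total detected count across replicates, and the mean
#' mapped read count.
#'
#' @param replicates Output of [subsample()] or [subsample_counts()].
#' @param catalog Gene catalog supplying the biotype split.
#' @param threshold Expression threshold on raw counts (count > threshold).
#' @return A `data.frame`, one row per fraction, sorted by increasing
#'   fraction: `fraction`, `mean_detected`, `mean_detected_coding`,
#'   `mean_detected_noncoding`, `cv_detected_percent`, `mean_mapped_reads`.
#' @export
detection_curve <- function(replicates, catalog, threshold = 3) {
  if (!length(replicates)) stop("no replicates supplied", call. = FALSE)
  coding <- stats::setNames(catalog$coding_class == "coding", catalog$gene_id)
  per_rep <- data.table::rbindlist(lapply(replicates, function(rep) {
    det <- rep$counts > threshold
    data.table::data.table(
      fraction = rep$fraction,
      detected = sum(det),
      detected_coding = sum(det & coding[names(rep$counts)]),
      detected_noncoding = sum(det & !coding[names(rep$counts)]),
      mapped = rep$n_mapped_reads
    )
  }))
  detected <- NULL # appease R CMD check; data.table NSE
  agg <- per_rep[, list(
    mean_detected = mean(detected),
    mean_detected_coding = mean(detected_coding),
    mean_detected_noncoding = mean(detected_noncoding),
    cv_detected_percent = if (.N > 1) 100 * stats::sd(detected) / mean(detected) else NA_real_,
    mean_mapped_reads = mean(mapped)
  ), by = "fraction"]
  agg <- agg[order(agg$fraction)]
  as.data.frame(agg)
}

#' Percent gene-expression variation (%GEV)
#'
#' Relative difference of a gene's subset expression from its reference
#' expression, as a percentage of the reference:
#' `((ref - subset) / ref) * 100`, with expression on the log2(CPM) scale.
#' Positive values mean the subset under-estimates the reference; a subset
#' value above the reference gives a negative %GEV.
#'
#' @param ref_log2cpm Reference (full-dataset) log2(CPM); must be nonzero.
#' @param subset_log2cpm Subset log2(CPM).
#' @return %GEV values (vectorized).
#' @export
gev <- function(ref_log2cpm, subset_log2cpm) {
  if (any(ref_log2cpm == 0))
    stop("%GEV undefined for reference log2(CPM) of exactly 0; ",
         "exclude such genes", call. = FALSE)
  (ref_log2cpm - subset_log2cpm) / ref_log2cpm * 100
}

#' Per-gene, per-replicate %GEV table
#'
#' For each fraction, identifies eligible genes -- detected (count >
#' `threshold`) in at least `ceiling(min_replicate_detection *
#' n_replicates)` replicates, detected in the reference, and with
#' reference log2(CPM) different from 0 (the formula divides by it) --
#' and emits one %GEV row per eligible gene per replicate in which that
#' gene is detected. Rows carry the gene's coding class and fixed
#' reference expression quartile.
#'
#' @param ref_expr Named reference log2(CPM) vector (`NA` = not
#'   expressed), typically `log2cpm(count_reads(...))[, 1]`.
#' @param replicates Output of [subsample()] / [subsample_counts()].
#' @param catalog Gene catalog.
#' @param quartiles Quartile table from [quartile_classes()] on the
#'   reference expression (computed internally when `NULL`).
#' @param threshold Expression threshold on raw counts.
#' @param min_replicate_detection Minimum fraction of replicates in which
#'   a gene must be detected to enter the table (default 0.8).
#' @return A `data.frame` with columns `gene_id`, `fraction`, `replicate`,
#'   `gev_percent`, `coding_class`, `quartile`. The number of genes
#'   excluded for reference log2(CPM) == 0 is recorded in attribute
#'   `n_ref_zero_excluded`.
#' @export
gev_table <- function(ref_expr, replicates, catalog, quartiles = NULL,
                      threshold = 3, min_replicate_detection = 0.8) {
  if (is.matrix(ref_expr)) {
    stopifnot(ncol(ref_expr) == 1)
    ref_expr <- stats::setNames(ref_expr[, 1], rownames(ref_expr))
  }
  if (is.null(quartiles)) quartiles <- quartile_classes(ref_expr, catalog)
  qmap <- stats::setNames(quartiles$quartile, quartiles$gene_id)
  cmap <- stats::setNames(catalog$coding_class, catalog$gene_id)
  ref_detected <- !is.na(ref_expr)
  ref_zero <- ref_detected & ref_expr == 0
  n_zero <- sum(ref_zero)
  if (n_zero > 0)
    message(n_zero, " gene(s) excluded from %GEV: reference log2(CPM) == 0")
  fractions <- unique(vapply(replicates, `[[`, numeric(1), "fraction"))
  pieces <- list()
  for (f in fractions) {
    reps <- Filter(function(r) r$fraction == f, replicates)
    n_rep <- length(reps)
    need <- ceiling(min_replicate_detection * n_rep)
    det_mat <- vapply(reps, function(r) r$counts[names(ref_expr)] > threshold,
                      logical(length(ref_expr)))
    eligible <- rowSums(det_mat) >= need & ref_detected & !ref_zero
    if (!any(eligible)) next
    genes <- names(ref_expr)[eligible]
    for (r in reps) {
      lib <- sum(r$counts)
      det_here <- genes[r$counts[genes] > threshold]
      if (!length(det_here)) next
      sub_expr <- log2(r$counts[det_here] / lib * 1e6)
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        gene_id = det_here,
        fraction = f,
        replicate = r$replicate,
        gev_percent = gev(ref_expr[det_here], sub_expr)
      )
    }
  }
  out <- if (length(pieces)) {
    as.data.frame(data.table::rbindlist(pieces))
  } else {
    data.frame(gene_id = character(0), fraction = numeric(0),
               replicate = integer(0), gev_percent = numeric(0))
  }
  out$coding_class <- unname(cmap[out$gene_id])
  out$quartile <- unname(qmap[out$gene_id])
  attr(out, "n_ref_zero_excluded") <- n_zero
  out
}

#' Summaries of the %GEV distributions
#'
#' Per fraction -- overall, per coding class, and per expression quartile
#' -- reports the median, interquartile range and mean absolute %GEV of
#' the pooled per-(gene, replicate) values. Additionally computes, for
#' each fraction, the Spearman rank correlation between the expression
#' quartile (Q1 = 1 .. Q4 = 4) and the per-gene mean absolute %GEV: a
#' negative value means highly expressed genes vary less.
#'
#' @param gevtab Table from [gev_table()].
#' @return A list with `by_fraction`, `by_coding_class`, `by_quartile`
#'   (`data.frame`s of summaries) and `quartile_correlation` (one Spearman
#'   rho per fraction).
#' @export
gev_summary <- function(gevtab) {
  if (!nrow(gevtab)) stop("empty %GEV table", call. = FALSE)
  dt <- data.table::as.data.table(gevtab)
  gev_percent <- gene_id <- quartile <- mean_abs_gev <- NULL
  summarize <- function(d, by) {
    s <- d[, list(
      n = .N,
      median_gev = stats::median(gev_percent),
      iqr_gev = stats::IQR(gev_percent),
      mean_abs_gev = mean(abs(gev_percent))
    ), by = by]
    as.data.frame(s[do.call(order, s[, by, with = FALSE])])
  }
  per_gene <- dt[, list(mean_abs_gev = mean(abs(gev_percent))),
                 by = c("fraction", "gene_id", "quartile")]
  qcor <- per_gene[, list(
    spearman_rho = {
      qnum <- as.integer(sub("^Q", "", quartile))
      if (length(unique(qnum)) > 1 && length(unique(mean_abs_gev)) > 1)
        stats::cor(qnum, mean_abs_gev, method = "spearman")
      else NA_real_
    }
  ), by = "fraction"]
  list(
    by_fraction = summarize(dt, "fraction"),
    by_coding_class = summarize(dt, c("fraction", "coding_class")),
    by_quartile = summarize(dt, c("fraction", "coding_class", "quartile")),
    quartile_correlation = as.data.frame(qcor[order(qcor$fraction)])
  )
}
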