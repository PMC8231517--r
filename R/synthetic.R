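#' Simulation configuration for a synthetic long-read RNA-seq dataset
#'
#' Bundles every parameter of the synthetic generator: the gene catalog
#' (size, coding/non-coding split, expression law), the read layer (number
#' of reads, mapped fraction, read-length and mean-quality laws) and the
#' optional barcode multiplexing.
#'
#' The defaults emulate a combined MinION cDNA run of human primary cells:
#' roughly 60/40 coding/non-coding genes, non-coding genes shifted toward
#' low expression, mean read length near 483 bp, about 58% of reads
#' assigned to a gene, and a mean-Phred distribution (normal, mean 10,
#' sd 3, truncated at 0) that straddles the Q = 7 quality cutoff.
#'
#' @param n_genes Number of genes in the catalog (>= 2).
#' @param coding_fraction Fraction of protein-coding genes, strictly in (0,1).
#' @param expression_meanlog Location (natural-log) of the log-normal
#'   abundance law for coding genes.
#' @param expression_sdlog Scale (natural-log) of the abundance law.
#' @param noncoding_shift Downward shift (natural-log units) of the
#'   non-coding location parameter; positive values put non-coding genes at
#'   lower expression.
#' @param n_reads Number of reads to simulate.
#' @param mapped_fraction Probability that a read is assigned to a gene,
#'   strictly in (0,1).
#' @param read_length_mean Target mean read length in bp (log-normal law).
#' @param read_length_sdlog Scale (natural-log) of the read-length law.
#' @param quality_mean,quality_sd Mean and sd of the mean-Phred law
#'   (normal truncated at 0).
#' @param n_barcodes Number of multiplexing barcodes (0 = no barcoding).
#' @param barcode_weights Barcode sampling proportions; must have length
#'   `n_barcodes` and sum to 1 (default: equal weights).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [generate_catalog()], [simulate_reads()]
#' @export
sim_config <- function(n_genes = 20000L,
                       coding_fraction = 0.62,
                       expression_meanlog = 0,
                       expression_sdlog = 1.5,
                       noncoding_shift = 1.5,
                       n_reads = 2000000L,
                       mapped_fraction = 0.58,
                       read_length_mean = 483,
                       read_length_sdlog = 0.45,
                       quality_mean = 10,
                       quality_sd = 3,
                       n_barcodes = 0L,
                       barcode_weights = NULL,
                       seed = 7L) {
  n_genes <- as.integer(n_genes)
  n_reads <- as.integer(n_reads)
  n_barcodes <- as.integer(n_barcodes)
  if (is.na(n_genes) || n_genes < 2L)
    stop("`n_genes` must be an integer >= 2", call. = FALSE)
  if (is.na(n_reads) || n_reads < 1L)
    stop("`n_reads` must be a positive integer", call. = FALSE)
  if (!is.numeric(coding_fraction) || coding_fraction <= 0 || coding_fraction >= 1)
    stop("`coding_fraction` must lie strictly in (0, 1)", call. = FALSE)
  if (!is.numeric(mapped_fraction) || mapped_fraction <= 0 || mapped_fraction > 1)
    stop("`mapped_fraction` must lie in (0, 1]", call. = FALSE)
  if (n_barcodes < 0L)
    stop("`n_barcodes` must be non-negative", call. = FALSE)
  if (is.null(barcode_weights)) {
    barcode_weights <- if (n_barcodes > 0L) rep(1 / n_barcodes, n_barcodes) else numeric(0)
  }
  if (length(barcode_weights) != n_barcodes)
    stop("`barcode_weights` must have length `n_barcodes`", call. = FALSE)
  if (n_barcodes > 0L && abs(sum(barcode_weights) - 1) > 1e-9)
    stop("`barcode_weights` must sum to 1 (tolerance 1e-9)", call. = FALSE)
  if (read_length_mean <= 0 || quality_sd <= 0 || expression_sdlog <= 0)
    stop("distribution parameters must be positive", call. = FALSE)
  structure(list(
    n_genes = n_genes,
    coding_fraction = coding_fraction,
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    noncoding_shift = noncoding_shift,
    n_reads = n_reads,
    mapped_fraction = mapped_fraction,
    read_length_mean = read_length_mean,
    read_length_sdlog = read_length_sdlog,
    quality_mean = quality_mean,
    quality_sd = quality_sd,
    n_barcodes = n_barcodes,
    barcode_weights = barcode_weights,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# round half away from zero; base round() is round-half-even
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Generate a synthetic gene catalog with abundance weights
#'
#' Draws a catalog of `n_genes` genes: exactly `round(n_genes *
#' coding_fraction)` protein-coding genes (half-up rounding), the remainder
#' split among the non-coding biotypes (lncRNA, ncRNA, pseudogene). Each
#' gene gets a relative abundance weight from a log-normal law; the
#' non-coding location parameter is shifted down by `noncoding_shift` so
#' non-coding genes sit at lower expression, as observed in poly-A
#' long-read libraries. Weights are normalized to sum to 1.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `gene_id`, `biotype`,
#'   `coding_class` (`"coding"`/`"noncoding"`) and `weight`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  n_coding <- as.integer(round_half_up(n * config$coding_fraction))
  n_nc <- n - n_coding
  withr::with_seed(config$seed, {
    biotype <- c(
      rep("protein_coding", n_coding),
      sample(c("lncRNA", "ncRNA", "pseudogene"), n_nc,
             replace = TRUE, prob = c(0.5, 0.25, 0.25))
    )
    meanlog <- ifelse(biotype == "protein_coding",
                      config$expression_meanlog,
                      config$expression_meanlog - config$noncoding_shift)
    w <- stats::rlnorm(n, meanlog = meanlog, sdlog = config$expression_sdlog)
  })
  w <- w / sum(w)
  data.frame(
    gene_id = sprintf("G%06d", seq_len(n)),
    biotype = biotype,
    coding_class = coding_class_of(biotype),
    weight = w,
    stringsAsFactors = FALSE
  )
}

#' Map biotypes to the coding/non-coding partition
#'
#' Protein-coding genes are `"coding"`; lncRNA, ncRNA and pseudogenes are
#' collapsed into `"noncoding"`.
#'
#' @param biotype Character vector of biotype labels.
#' @return Character vector of `"coding"`/`"noncoding"`.
#' @export
coding_class_of <- function(biotype) {
  valid <- c("protein_coding", "lncRNA", "ncRNA", "pseudogene")
  bad <- setdiff(unique(biotype), valid)
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ifelse(biotype == "protein_coding", "coding", "noncoding")
}

# exact truncated normal (lower bound only) via inverse CDF
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate a read-assignment table
#'
#' Generates `n_reads` read records. Each read is mapped (assigned to a
#' gene) with probability `mapped_fraction`; mapped reads are assigned to
#' genes multinomially by the catalog abundance weights. Lengths are
#' log-normal around the target mean; mean Phred qualities follow a normal
#' law truncated at 0. With `n_barcodes > 0`, every read receives a barcode
#' multinomially by `barcode_weights`. Output is fully reproducible from
#' `config$seed`.
#'
#' Reads are atomic records (no base-level sequence): every downstream
#' statistic consumes only the read-to-gene assignment, length, quality and
#' barcode.
#'
#' @param catalog Catalog from [generate_catalog()].
#' @param config The same [sim_config()].
#' @return A `data.frame` with columns `read_id`, `gene_id` (`NA` when
#'   unmapped), `length` (bp), `mean_q` (Phred), `barcode` (`NA` when
#'   unbarcoded).
#' @export
simulate_reads <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(catalog) || nrow(catalog) == 0L)
    stop("catalog must be non-empty", call. = FALSE)
  n <- config$n_reads
  mu_len <- log(config$read_length_mean) - config$read_length_sdlog^2 / 2
  withr::with_seed(config$seed + 1L, {
    mapped <- stats::runif(n) < config$mapped_fraction
    gene <- rep(NA_character_, n)
    n_map <- sum(mapped)
    if (n_map > 0L) {
      gene[mapped] <- sample(catalog$gene_id, n_map,
                             replace = TRUE, prob = catalog$weight)
    }
    len <- pmax(1L, as.integer(round_half_up(
      stats::rlnorm(n, meanlog = mu_len, sdlog = config$read_length_sdlog))))
    q <- rtruncnorm_lower(n, config$quality_mean, config$quality_sd)
    bc <- if (config$n_barcodes > 0L) {
      sample(sprintf("barcode%02d", seq_len(config$n_barcodes)), n,
             replace = TRUE, prob = config$barcode_weights)
    } else {
      rep(NA_character_, n)
    }
  })
  data.frame(
    read_id = sprintf("read%08d", seq_len(n)),
    gene_id = gene,
    length = len,
    mean_q = q,
    barcode = bc,
    stringsAsFactors = FALSE
  )
}

NULL_SENTINEL <- "*"

#' Read/write tab-separated read and catalog tables
#'
#' Plain UTF-8 TSV with a mandatory header row. Unmapped genes and absent
#' barcodes are encoded with the literal sentinel `"*"` (echoing SAM's
#' unmapped convention) and round-trip to `NA`.
#'
#' @param reads,catalog Tables as produced by [simulate_reads()] /
#'   [generate_catalog()].
#' @param path File path.
#' @return The readers return the parsed `data.frame`; the writers return
#'   `path` invisibly.
#' @name read_tables_io
NULL

#' @rdname read_tables_io
#' @export
write_reads <- function(reads, path) {
  out <- reads
  out$gene_id[is.na(out$gene_id)] <- NULL_SENTINEL
  out$barcode[is.na(out$barcode)] <- NULL_SENTINEL
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_tables_io
#' @export
read_reads <- function(path) {
  x <- read_tsv_checked(path, c("read_id", "gene_id", "length", "mean_q", "barcode"))
  x$gene_id[x$gene_id == NULL_SENTINEL] <- NA_character_
  x$barcode[x$barcode == NULL_SENTINEL] <- NA_character_
  check_numeric_column(x, path, "length", integer_only = TRUE)
  check_numeric_column(x, path, "mean_q")
  x$length <- as.integer(x$length)
  x$mean_q <- as.numeric(x$mean_q)
  if (any(x$length < 1L)) stop("read lengths must be >= 1 in ", path, call. = FALSE)
  if (any(x$mean_q < 0)) stop("mean_q must be >= 0 in ", path, call. = FALSE)
  x
}

#' @rdname read_tables_io
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("gene_id", "biotype", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_tables_io
#' @export
read_catalog <- function(path) {
  x <- read_tsv_checked(path, c("gene_id", "biotype", "weight"))
  check_numeric_column(x, path, "weight")
  x$weight <- as.numeric(x$weight)
  if (anyDuplicated(x$gene_id))
    stop("duplicate gene_id values in ", path, call. = FALSE)
  x$coding_class <- coding_class_of(x$biotype)
  x[, c("gene_id", "biotype", "coding_class", "weight")]
}

# read a header-checked TSV as all-character columns
read_tsv_checked <- function(path, expected_cols) {
  x <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!identical(colnames(x), expected_cols))
    stop("unexpected header in ", path, ": expected ",
         paste(expected_cols, collapse = ", "), call. = FALSE)
  x
}

# report the first offending line (1-based, counting the header as line 1)
check_numeric_column <- function(x, path, col, integer_only = FALSE) {
  v <- x[[col]]
  pattern <- if (integer_only) "^-?[0-9]+$" else "^-?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?$"
  bad <- which(!grepl(pattern, v))
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1] + 1L, ": field `", col,
         "` value \"", v[bad[1]], "\" is not ",
         if (integer_only) "an integer" else "numeric", call. = FALSE)
  invisible(TRUE)
}
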