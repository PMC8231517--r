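#' Pipeline run configuration
#'
#' Bundles a simulation block, a subsampling block and the analysis
#' thresholds for [run_pipeline()]. Any field can be overridden; defaults
#' give the demo run (20,000 genes, 2,000,000 reads, seed 7).
#'
#' @param sim A [sim_config()].
#' @param subsets A [subset_spec()].
#' @param quality_threshold Minimum mean Phred (reads below are dropped).
#' @param expression_threshold Raw-count threshold; expressed = count > it.
#' @param min_replicate_detection Minimum replicate-detection fraction for
#'   %GEV eligibility.
#' @param write_plots Also emit PNG plots (saturation curve, %GEV
#'   medians). Numeric TSV/JSON remains the primary output.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       subsets = subset_spec(base_seed = sim$seed),
                       quality_threshold = 7,
                       expression_threshold = 3,
                       min_replicate_detection = 0.8,
                       write_plots = FALSE) {
  if (quality_threshold < 0) stop("quality threshold must be >= 0", call. = FALSE)
  if (expression_threshold < 0) stop("expression threshold must be >= 0", call. = FALSE)
  if (min_replicate_detection <= 0 || min_replicate_detection > 1)
    stop("min_replicate_detection must lie in (0, 1]", call. = FALSE)
  structure(list(sim = sim, subsets = subsets,
                 quality_threshold = quality_threshold,
                 expression_threshold = expression_threshold,
                 min_replicate_detection = min_replicate_detection,
                 write_plots = isTRUE(write_plots)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full depth-evaluation pipeline
#'
#' Executes simulate -> quality filter -> count -> quantify -> replicated
#' subsampling -> saturation/%GEV profiling -> concordance, logging
#' read/gene conservation counters at every stage boundary, and writes all
#' result tables (TSV) plus a machine-readable JSON summary of the
#' headline numbers into `out_dir`. Fully reproducible from the
#' configuration (which carries the seeds).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and just returns the results.
#' @return Invisibly, a list with the catalog, filtered read stats, the
#'   detection curve, %GEV summaries, concordance results and the summary
#'   list written to JSON.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate"
  res <- tryCatch({
    catalog <- generate_catalog(config$sim)
    reads <- simulate_reads(catalog, config$sim)
    stage_log(stage, nrow(reads), " reads over ", nrow(catalog), " genes")

    stage <- "filter"
    passed <- quality_filter(reads, config$quality_threshold)
    stage_log(stage, attr(passed, "n_pass"), "/", nrow(reads),
              " reads pass mean Phred >= ", config$quality_threshold,
              sprintf(" (%.1f%%)", 100 * attr(passed, "pass_fraction")))

    stage <- "count"
    counts <- count_reads(passed, catalog, "reference")
    stage_log(stage, sum(counts), " mapped reads counted (",
              sprintf("%.1f%%", 100 * sum(counts) / nrow(passed)),
              " of passed)")

    stage <- "quantify"
    ref_expr <- log2cpm(counts, config$expression_threshold)[, 1]
    n_expr <- sum(!is.na(ref_expr))
    stage_log(stage, n_expr, " expressed genes (count > ",
              config$expression_threshold, ")")
    quart <- quartile_classes(ref_expr, catalog)

    stage <- "profile"
    reps <- subsample(passed, config$subsets, catalog)
    curve <- detection_curve(reps, catalog, config$expression_threshold)
    gevtab <- gev_table(ref_expr, reps, catalog, quart,
                        config$expression_threshold,
                        config$min_replicate_detection)
    gsum <- gev_summary(gevtab)
    stage_log(stage, length(reps), " subset replicates; ",
              nrow(gevtab), " %GEV rows")

    stage <- "concord"
    pair_seed <- config$subsets$base_seed + 90001L
    half <- withr::with_seed(pair_seed, sample.int(nrow(passed), round_half_up(nrow(passed) / 2)))
    ca <- count_reads(passed[half, , drop = FALSE], catalog, "halfA")
    cb <- count_reads(passed[-half, , drop = FALSE], catalog, "halfB")
    pr <- pair_expression(log2cpm(ca, config$expression_threshold)[, 1],
                          log2cpm(cb, config$expression_threshold)[, 1])
    split_cor <- pearson(pr$x, pr$y)
    stage_log(stage, "split-half correlation r = ",
              sprintf("%.4f", split_cor$r))

    summary <- list(
      n_genes = nrow(catalog),
      n_reads = nrow(reads),
      n_passed_reads = attr(passed, "n_pass"),
      pass_fraction = attr(passed, "pass_fraction"),
      n_mapped_reads = sum(counts),
      n_expressed_genes = n_expr,
      detection_curve = curve,
      gev_by_fraction = gsum$by_fraction,
      gev_quartile_correlation = gsum$quartile_correlation,
      split_half_r = split_cor$r
    )
    list(catalog = catalog, counts = counts, ref_expr = ref_expr,
         quartiles = quart, replicates = reps, detection_curve = curve,
         gev_table = gevtab, gev_summary = gsum, split_half = split_cor,
         summary = summary)
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wtsv(res$detection_curve, "detection_curve.tsv")
    wtsv(res$gev_table, "gev_table.tsv")
    wtsv(res$gev_summary$by_fraction, "gev_summary_by_fraction.tsv")
    wtsv(res$gev_summary$by_quartile, "gev_summary_by_quartile.tsv")
    wtsv(res$quartiles, "quartile_classes.tsv")
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$write_plots) {
      grDevices::png(file.path(out_dir, "detection_curve.png"), 800, 600)
      plot_detection_curve(res$detection_curve)
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "gev_by_fraction.png"), 800, 600)
      plot_gev_summary(res$gev_summary$by_fraction)
      grDevices::dev.off()
    }
  }
  invisible(res)
}

#' Expected subset sizes for a depth ladder
#'
#' Applies [subset_size()] over a vector of fractions, labelling each row
#' with the conventional DSxx dataset name. With a 48,495,343-read library
#' and the standard ladder this reproduces published per-subset totals
#' exactly, including the half-up rounding cases.
#'
#' @param total_reads Total read count of the full dataset.
#' @param fractions Depth fractions (default 100% down to 5%).
#' @return `data.frame` with `dataset`, `fraction`, `expected_total_reads`.
#' @export
validate_against_table1 <- function(total_reads,
                                    fractions = c(1, 0.9, 0.8, 0.7, 0.6, 0.5,
                                                  0.4, 0.3, 0.2, 0.1, 0.05)) {
  data.frame(
    dataset = sprintf("DS%g", 100 * fractions),
    fraction = fractions,
    expected_total_reads = subset_size(total_reads, fractions),
    stringsAsFactors = FALSE
  )
}

#' Base-graphics saturation and %GEV plots
#'
#' Minimal line plots of the detection curve and of the per-fraction
#' median %GEV; cosmetic styling is intentionally out of scope.
#'
#' @param curve Output of [detection_curve()].
#' @param by_fraction `by_fraction` element of [gev_summary()].
#' @return Invisibly `NULL`; called for the plot side effect.
#' @name depthsat_plots
NULL

#' @rdname depthsat_plots
#' @export
plot_detection_curve <- function(curve) {
  graphics::plot(curve$fraction, curve$mean_detected, type = "b", pch = 16,
                 xlab = "subset fraction", ylab = "mean detected genes",
                 ylim = c(0, max(curve$mean_detected)))
  graphics::lines(curve$fraction, curve$mean_detected_coding,
                  type = "b", pch = 16, col = "red")
  graphics::lines(curve$fraction, curve$mean_detected_noncoding,
                  type = "b", pch = 16, col = "darkgreen")
  graphics::legend("bottomright", c("total", "coding", "non-coding"),
                   col = c("black", "red", "darkgreen"), lty = 1, pch = 16)
  invisible(NULL)
}

#' @rdname depthsat_plots
#' @export
plot_gev_summary <- function(by_fraction) {
  graphics::plot(by_fraction$fraction, by_fraction$median_gev, type = "b",
                 pch = 16, xlab = "subset fraction", ylab = "median %GEV")
  graphics::abline(h = 0, lty = 2)
  invisible(NULL)
}
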