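# small constructors shared across test files

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 200L, coding_fraction = 0.6, n_reads = 20000L,
         mapped_fraction = 0.6, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# a read table built directly from gene assignments (all Q above cutoff)
make_reads <- function(gene_ids, mean_q = 12, barcode = NA_character_) {
  n <- length(gene_ids)
  data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    gene_id = gene_ids,
    length = rep(100L, n),
    mean_q = rep_len(mean_q, n),
    barcode = rep_len(barcode, n),
    stringsAsFactors = FALSE
  )
}

# an all-coding catalog with uniform weights, for count-level toys
make_catalog <- function(gene_ids, biotype = "protein_coding") {
  data.frame(
    gene_id = gene_ids,
    biotype = rep_len(biotype, length(gene_ids)),
    coding_class = coding_class_of(rep_len(biotype, length(gene_ids))),
    weight = rep(1 / length(gene_ids), length(gene_ids)),
    stringsAsFactors = FALSE
  )
}

# moderately sized simulated dataset reused by several suites
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 5000L, n_reads = 600000L, seed = 42L)
      catalog <- generate_catalog(cfg)
      reads <- simulate_reads(catalog, cfg)
      passed <- quality_filter(reads)
      cache <<- list(config = cfg, catalog = catalog,
                     reads = reads, passed = passed)
    }
    cache
  }
})
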