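# published depth ladder of a 48,495,343-read library (used as frozen
# oracle values for the half-up rounding rule)
TOTAL_READS_REF <- 48495343
LADDER_FRACTIONS <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
LADDER_SIZES <- c(48495343, 43645809, 38796274, 33946740, 29097206, 24247672,
                  19398137, 14548603, 9699069, 4849534, 2424767)

test_that("subset_size rounds half away from zero", {
  expect_equal(subset_size(TOTAL_READS_REF, LADDER_FRACTIONS), LADDER_SIZES)
  # the two exercised half-up cases
  expect_equal(subset_size(TOTAL_READS_REF, 0.5), 24247672)
  expect_equal(subset_size(TOTAL_READS_REF, 0.3), 14548603)
  expect_equal(subset_size(100, 1), 100)
  expect_equal(subset_size(100, 0.05), 5)
  expect_error(subset_size(100, 0), "fraction")
  expect_error(subset_size(100, 1.5), "fraction")
})

test_that("subset_spec validates and derives collision-free seeds", {
  expect_error(subset_spec(fractions = c(0.5, 0)), "fractions")
  expect_error(subset_spec(n_replicates = 0), "n_replicates")
  spec <- subset_spec()
  seeds <- unlist(lapply(seq_along(spec$fractions), function(fi)
    vapply(seq_len(spec$n_replicates), function(r)
      depthsat:::replicate_seed(spec, fi, r), numeric(1))))
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("subsample draws exact-size subsets without replacement", {
  catalog <- make_catalog(c("g1", "g2"))
  reads <- make_reads(c(rep("g1", 50), rep("g2", 950)))
  full <- subsample(reads, subset_spec(1, 1, 1L), catalog)
  expect_identical(full[[1]]$counts, c(g1 = 50L, g2 = 950L))
  expect_identical(full[[1]]$n_total_reads, 1000)
  expect_identical(full[[1]]$n_mapped_reads, 1000L)

  # hypergeometric oracle: mean subset count of a c=50 gene at 10% of 1000
  reps <- subsample(reads, subset_spec(0.1, 2000, 7L), catalog)
  g1 <- vapply(reps, function(r) r$counts[["g1"]], numeric(1))
  v <- 100 * (50 / 1000) * (1 - 50 / 1000) * (1000 - 100) / (1000 - 1)
  expect_lt(abs(mean(g1) - 5), 3 * sqrt(v / 2000))

  # conservation: counts always sum to the mapped subset size
  expect_true(all(vapply(reps, function(r)
    sum(r$counts) == r$n_mapped_reads, logical(1))))
  expect_true(all(vapply(reps, function(r)
    r$n_mapped_reads <= r$n_total_reads, logical(1))))

  # replicates with distinct seeds differ; same spec reproduces exactly
  ten <- make_reads(c(rep("g1", 5), rep("g2", 5)))
  reps2 <- subsample(ten, subset_spec(0.5, 50, 3L), catalog)
  mats <- vapply(reps2, `[[`, integer(2), "counts")
  expect_gt(nrow(unique(t(mats))), 1)
  expect_identical(subsample(ten, subset_spec(0.5, 50, 3L), catalog), reps2)

  expect_error(subsample(reads[0, ], subset_spec(0.5, 1, 1L), catalog),
               "empty")
})

test_that("subsample_counts is a multivariate hypergeometric draw", {
  expect_identical(
    subsample_counts(c(g1 = 10L, g2 = 0L), subset_spec(0.5, 3, 1L))[[1]]$counts,
    c(g1 = 5L, g2 = 0L))
  expect_identical(
    subsample_counts(c(g1 = 7L, g2 = 3L), subset_spec(1, 1, 1L))[[1]]$counts,
    c(g1 = 7L, g2 = 3L))
  expect_error(subsample_counts(c(g1 = 0L), subset_spec(0.5, 1, 1L)),
               "subset size 0")

  # distributional equivalence with the read-level route on a 5-gene toy
  k <- c(g1 = 30L, g2 = 25L, g3 = 20L, g4 = 15L, g5 = 10L)
  n_draws <- 5000L
  cl <- subsample_counts(k, subset_spec(0.3, n_draws, 11L))
  reads <- make_reads(rep(names(k), k))
  rl <- subsample(reads, subset_spec(0.3, n_draws, 12L), make_catalog(names(k)))
  tot_cl <- Reduce(`+`, lapply(cl, `[[`, "counts"))
  tot_rl <- Reduce(`+`, lapply(rl, `[[`, "counts"))
  eq <- suppressWarnings(chisq.test(rbind(tot_cl, tot_rl)))
  expect_gt(eq$p.value, 0.001)
})

test_that("detection_curve summarizes detection by fraction and biotype", {
  sim <- shared_sim()
  spec <- subset_spec(c(0.9, 0.5, 0.1), n_replicates = 5, base_seed = 2L)
  reps <- subsample(sim$passed, spec, sim$catalog)
  curve <- detection_curve(reps, sim$catalog)
  expect_identical(curve$fraction, c(0.1, 0.5, 0.9))
  expect_equal(curve$mean_detected,
               curve$mean_detected_coding + curve$mean_detected_noncoding)
  expect_true(all(diff(curve$mean_detected) > 0))

  # a full-fraction replicate detects exactly the reference gene set
  full <- subsample(sim$passed, subset_spec(1, 1, 1L), sim$catalog)
  ref_counts <- count_reads(sim$passed, sim$catalog)
  expect_identical(detection_curve(full, sim$catalog)$mean_detected,
                   as.numeric(sum(ref_counts > 3)))
})

test_that("Monte-Carlo detection frequency matches the hypergeometric tail", {
  k <- c(target = 4L, rest = 96L)
  p_exact <- phyper(3, 4, 96, 5, lower.tail = FALSE)
  reps <- subsample_counts(k, subset_spec(0.05, 5000, 5L))
  freq <- mean(vapply(reps, function(r) r$counts[["target"]] > 3, logical(1)))
  se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(freq - p_exact), 3 * se)
  # full subset: detection certain
  full <- subsample_counts(k, subset_spec(1, 10, 5L))
  expect_true(all(vapply(full, function(r) r$counts[["target"]] > 3,
                         logical(1))))
})

test_that("gev implements the relative-difference contract", {
  expect_identical(gev(10, 10), 0)
  expect_identical(gev(10, 5), 50)
  expect_identical(gev(5, 10), -100)
  x <- c(2.5, -4, 17)
  expect_equal(gev(x, x), c(0, 0, 0))
  expect_error(gev(0, 1), "undefined")
  expect_error(gev(c(1, 0), c(1, 1)), "undefined")
})

test_that("gev_table applies the 80%-replicate eligibility rule", {
  genes <- sprintf("g%02d", 1:8)
  catalog <- make_catalog(genes)
  ref_counts <- matrix(c(100L, 90L, 80L, 70L, 60L, 50L, 40L, 30L), ncol = 1,
                       dimnames = list(genes, "ref"))
  ref_expr <- log2cpm(ref_counts)[, 1]
  quart <- quartile_classes(ref_expr, catalog)

  # hand-built replicates: g01 detected in 10/10, g02 in 7/10, rest in 10/10
  mk_rep <- function(i, drop_g02) {
    counts <- setNames(c(50L, if (drop_g02) 2L else 45L, 40L, 35L,
                         30L, 25L, 20L, 15L), genes)
    list(fraction = 0.5, replicate = i, seed = i, counts = counts,
         n_total_reads = sum(counts), n_mapped_reads = sum(counts))
  }
  reps <- lapply(1:10, function(i) mk_rep(i, drop_g02 = i <= 3))
  tab <- gev_table(ref_expr, reps, catalog, quart)
  expect_false("g02" %in% tab$gene_id)              # 7/10 < ceil(0.8 * 10)
  expect_identical(sum(tab$gene_id == "g01"), 10L)  # one row per replicate
  expect_true(all(c("coding_class", "quartile") %in% colnames(tab)))

  # subset identical to reference: all %GEV are zero
  full <- lapply(1, function(i) list(
    fraction = 1, replicate = 1L, seed = 1L,
    counts = setNames(ref_counts[, 1], genes),
    n_total_reads = sum(ref_counts), n_mapped_reads = sum(ref_counts)))
  tab_full <- gev_table(ref_expr, full, catalog, quart)
  expect_identical(nrow(tab_full), 8L)
  expect_equal(tab_full$gev_percent, rep(0, 8))

  # reference log2(CPM) == 0 (CPM exactly 1) is excluded with a message
  z_counts <- matrix(c(4L, 3993996L, rep(1000L, 6)), ncol = 1,
                     dimnames = list(genes, "ref")) # sums to exactly 4e6
  z_expr <- log2cpm(z_counts)[, 1]
  z_reps <- lapply(1, function(i) list(
    fraction = 1, replicate = 1L, seed = 1L,
    counts = setNames(z_counts[, 1], genes),
    n_total_reads = sum(z_counts), n_mapped_reads = sum(z_counts)))
  expect_message(
    z_tab <- gev_table(z_expr, z_reps, catalog, quart),
    "log2\\(CPM\\) == 0")
  expect_false("g01" %in% z_tab$gene_id)
  expect_identical(attr(z_tab, "n_ref_zero_excluded"), 1L)
})

test_that("gev_summary aggregates distributions and the quartile correlation", {
  tab <- data.frame(
    gene_id = rep(c("a", "b", "c", "d"), each = 2),
    fraction = 0.5,
    replicate = rep(1:2, 4),
    gev_percent = rep(0, 8),
    coding_class = "coding",
    quartile = rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  s <- gev_summary(tab)
  expect_equal(s$by_fraction$median_gev, 0)
  expect_equal(s$by_fraction$iqr_gev, 0)
  expect_equal(s$by_fraction$mean_abs_gev, 0)
  expect_true(is.na(s$quartile_correlation$spearman_rho)) # no spread

  # |%GEV| declining across quartiles gives a negative rank correlation
  tab$gev_percent <- rep(c(40, -30, 20, 10, -8, 6, 2, -1))
  s2 <- gev_summary(tab)
  expect_lt(s2$quartile_correlation$spearman_rho, 0)
  expect_error(gev_summary(tab[0, ]), "empty")
})
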