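# depthsat

How many reads does a long-read RNA-seq experiment need? `depthsat`
answers this question for Nanopore-style cDNA sequencing of bulk RNA by
measuring, as a function of sequencing depth, (i) how many genes are
detected and (ii) how stable their expression estimates are. It is aimed
at users designing MinION-class experiments who must trade sequencing
depth (cost, run time) against sensitivity — particularly for non-coding
genes, which sit at low expression and saturate last.

## What it computes

Starting from a reference library of quality-passed reads (real counts
via a featureCounts-style table, or fully synthetic data from the
built-in generator), the package:

1. **Subsamples** the library at a ladder of fractions (default 90% down
   to 5%), 10 random replicates each, drawn uniformly without
   replacement. Subset sizes use round-half-up:
   `n_f = ⌊f · N + 0.5⌋`.
2. **Quantifies** every subset: counts per million
   `CPM_g = c_g / Σc · 10⁶`, expression as `log₂(CPM)`, and a gene is
   *expressed* when its raw count is strictly greater than 3.
3. Builds the **detection saturation curve** — mean detected genes
   (total / coding / non-coding) and replicate CV per fraction.
4. Computes the per-gene **expression variation**
   `%GEV = (log₂(CPM_ref) − log₂(CPM_subset)) / log₂(CPM_ref) × 100`,
   restricted to genes detected in at least 80% of a fraction's
   replicates (and with nonzero reference `log₂(CPM)`), stratified by
   biotype and by reference expression quartile (Q1 low … Q4 high).
5. Runs **concordance checks**: Pearson correlations between replicate
   subsets, between each barcode of a multiplexed run and an equal-size
   random subset, and between `log₂(CPM)` and qPCR `dCt`
   (`Ct_target − Ct_GAPDH`) panels.

The synthetic generator produces atomic read records (gene assignment,
length, mean Phred quality, optional barcode) with log-normal gene
abundances (non-coding genes shifted down), ~58% of reads mapped, mean
read length near 483 bp and a quality law straddling the Q = 7 cutoff —
the statistical structure of a deep multiplexed MinION cDNA run.

## Worked example

```r
library(depthsat)
cfg <- run_config(
  sim     = sim_config(n_genes = 2000, n_reads = 200000, seed = 7),
  subsets = subset_spec(c(0.9, 0.5, 0.2, 0.05), n_replicates = 10, base_seed = 7))
res <- run_pipeline(cfg)   # pass out_dir = "results/" to also write TSV/JSON
res$detection_curve
```

```
[filter] 168326/200000 reads pass mean Phred >= 7 (84.2%)
[count] 97645 mapped reads counted (58.0% of passed)
[quantify] 1528 expressed genes (count > 3)
[profile] 40 subset replicates; 34489 %GEV rows

  fraction mean_detected mean_detected_coding mean_detected_noncoding cv_detected_percent mean_mapped_reads
1     0.05         322.1                282.6                    39.5              2.0356              4886
2     0.20         840.8                679.6                   161.2              1.2509             19529
3     0.50        1247.8                935.4                   312.4              0.8745             48792
4     0.90        1489.9               1059.7                   430.2              0.3444             87913
```

Detection saturates with depth (322 genes at 5% of the library vs 1490
at 90%) and non-coding genes saturate last — at 5% depth only 39.5 of
~570 detectable non-coding genes are found. Expression stability behaves
the same way:

```r
res$gev_summary$by_fraction
```

```
  fraction     n median_gev iqr_gev mean_abs_gev
1     0.05  2093    -0.1204    4.74         3.01
2     0.20  6719    -0.1025    4.40         2.98
3     0.50 11196    -0.0277    3.45         2.49
4     0.90 14481    -0.0870    1.55         1.25
```

Mean |%GEV| falls from 3.0% at 5% depth to 1.25% at 90% depth, and the
Spearman correlation between expression quartile and per-gene mean
|%GEV| is negative at every fraction (−0.61 to −0.85 here): highly
expressed genes are quantified more reliably.

`validate_against_table1(48495343)` expands the depth ladder of a
48,495,343-read library, e.g. DS50 = 24,247,672 and DS30 = 14,548,603
(the two rows that exercise the half-up rounding rule).

A command-line interface wrapping the same stages
(`simulate | filter | demux | count | quantify | profile | concord | run`)
is installed at `system.file("cli", "depthsat.R", package = "depthsat")`.

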