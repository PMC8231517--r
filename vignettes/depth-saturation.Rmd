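---
title: "Sequencing-depth saturation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequencing-depth saturation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-read cDNA sequencing on pocket-size nanopore devices trades depth
for convenience: a single flow cell yields on the order of 10–15 million
reads, far below a typical short-read run. Before committing to a study
design, a user wants to know how the number of detected genes and the
stability of their expression estimates degrade as reads are removed —
overall, and separately for protein-coding and non-coding genes, because
non-coding transcripts sit at low abundance and are the first casualties
of shallow sequencing.

`depthsat` frames this as a resampling experiment on a deep reference
library. Everything downstream of read counting is deterministic given
the subsampled counts, so the package operates on *read-assignment
tables* (read → gene, length, mean Phred quality, optional barcode) and
never touches base-level sequence. Alignment and counting are upstream
concerns; a featureCounts-style table can be ingested directly with
`read_featurecounts_table()`.

# The procedure

Let the reference library contain $N$ quality-passed reads. For each
fraction $f$ in a ladder (default $0.9, 0.8, \dots, 0.1, 0.05$) and each
of $R$ replicates (default 10), a subset of exactly

$$ n_f = \lfloor f \cdot N + 0.5 \rfloor $$

reads is drawn uniformly **without replacement** from all passed reads
(mapped or not), and per-gene counts are recomputed on the subset.
Sampling passed reads — rather than mapped reads — makes the subset's
total size scale exactly with $f$ while its mapped count is random,
which is how published per-subset read totals behave. Rounding is *half
away from zero*; this is the only convention that reproduces the
published ladder of a 48,495,343-read library (e.g. $f = 0.5$ gives
24,247,671.5 → 24,247,672), and the test suite pins all eleven values.

Per sample, expression is counts per million,
$\mathrm{CPM}_g = c_g / \sum_h c_h \times 10^6$, reported as
$\log_2(\mathrm{CPM})$, and a gene is **expressed** when its raw count
is strictly greater than 3 (i.e. $c_g \ge 4$). No pseudocount is added:
expressed genes always have positive CPM, and non-expressed entries are
`NA` rather than 0.

## Detection saturation

`detection_curve()` reports, per fraction, the mean number of expressed
genes across replicates (total, coding, non-coding) and the coefficient
of variation of that number. Per-gene subset counts are exactly
multivariate hypergeometric given the reference counts, so detection
probabilities have a closed form ($P(X_g > 3)$ with
$X_g \sim \mathrm{Hypergeom}(N, c_g, n_f)$) that the tests use as an
independent oracle, and mean detection is monotone in $f$ up to
replicate noise.

## Expression variation (%GEV)

For a gene $j$ and a subset replicate, the expression variation is the
relative difference from the reference on the log scale:

$$ \%\mathrm{GEV}_j \;=\;
   \frac{\log_2(\mathrm{CPM}_{\mathrm{ref},j}) -
         \log_2(\mathrm{CPM}_{\mathrm{sub},j})}
        {\log_2(\mathrm{CPM}_{\mathrm{ref},j})} \times 100 .$$

The printed form of this formula in the literature has ambiguous
parenthesization; we implement the relative-difference reading above,
the only one under which the statistic is a percentage of the reference
value. The sign convention follows: a subset that *over*-estimates the
reference gives a negative %GEV.

Three eligibility rules restrict the table (`gev_table()`):

* the gene is expressed in at least $\lceil 0.8 R \rceil$ of the
  fraction's replicates (with $R = 10$: 8);
* the gene is expressed in the reference (guaranteed for any gene
  expressed in a subset, since subset counts never exceed reference
  counts — asserted as an invariant);
* the reference $\log_2(\mathrm{CPM})$ is not exactly 0 (CPM exactly 1),
  because the formula divides by it. Such genes are excluded and their
  number is reported (`attr(tab, "n_ref_zero_excluded")`).

One %GEV row is emitted per eligible gene per replicate in which it is
expressed; the per-fraction violin-style distributions summarize these
pooled rows. Whether the original analysis pooled per-replicate values
or first averaged per gene is not documented; we default to pooled rows
and additionally provide the per-gene mean |%GEV|, which feeds the
quartile correlation below.

## Expression quartiles

`quartile_classes()` ranks the detected genes of the reference by
$\log_2(\mathrm{CPM})$ and cuts at the 25/50/75 rank percentiles into Q1
(low) … Q4 (high). Ties are broken by a stable sort on (value, gene id)
so class sizes are reproducible and differ by at most one. Two variants
exist because they answer different questions:

* `by_class = TRUE` (default): coding and non-coding genes are ranked
  *separately*. This is the stratification used for the %GEV-by-quartile
  analysis, where each biotype is compared against its own expression
  range.
* `by_class = FALSE`: one pooled ranking. Only this variant can express
  "non-coding genes are over-represented in the low-expression class" —
  under per-class quartiles every class contains ~25% of each biotype by
  construction, so the claim would be vacuous. The acceptance suite uses
  the pooled variant for the enrichment test and the per-class variant
  everywhere else.

The quartile labels are computed once on the reference and held fixed
across subsets. `gev_summary()` reports, per fraction, the Spearman rank
correlation between quartile (Q1 = 1 … Q4 = 4) and per-gene mean |%GEV|;
sampling theory predicts it negative, since the variance of
$\log$-scale abundance estimates shrinks with the count.

## Multiplexing and concordance

`demultiplex()` splits reads on their (exact) barcode field; trimming
and mismatch-tolerant matching are upstream concerns. `barcode_stats()`
summarizes a run the way multiplexed experiments are reported: mean
total reads per barcode and the CV of the per-barcode expressed-gene
numbers. The CV uses the **sample** standard deviation ($n-1$
denominator) as a percentage of the mean — verified against a published
six-barcode summary, which only that convention reproduces
(5.27% vs 4.81% with the population SD; the published table prints
5.26%, apparently truncated, and the test allows 0.01).

`multiplex_vs_subset()` draws one random subset of the reference whose
size equals the mean per-barcode read count and Pearson-correlates each
barcode's $\log_2(\mathrm{CPM})$ against it over the intersection of
expressed genes. Intersection is the default pairing everywhere
(`pair_expression()`) because $\log_2(\mathrm{CPM})$ is undefined for
non-expressed genes; a `union-zero` mode exists for sensitivity checks
and flags imputed entries.

`qpcr_concordance()` correlates $\log_2(\mathrm{CPM})$ with qPCR
$\mathrm{dCt} = Ct_\mathrm{target} - Ct_\mathrm{reference}$. Since
higher expression means *lower* dCt, the natural sign of the correlation
is negative; published reports sometimes quote the positive magnitude
without stating a transformation, so both the signed $r$ and $|r|$ are
returned, with $|r|$ as the headline.

# The synthetic generator

`sim_config()` states the world the pipeline is tested in. Reads are
atomic; the defaults emulate a deep multiplexed nanopore cDNA run of
human primary cells:

| parameter | default | unit | why |
|---|---|---|---|
| `n_genes` | 20,000 | genes | order of detected genes in a deep poly-A library |
| `coding_fraction` | 0.62 | — | >60% of detected genes are protein-coding |
| abundance law | log-normal, `sdlog` 1.5 | — | heavy-tailed bulk expression; `sdlog` is a stand-in (the true cellular law is unknown) |
| `noncoding_shift` | 1.5 | natural-log units | puts non-coding genes at lower expression; magnitude free, qualitative claim only |
| `n_reads` | 2,000,000 | reads | a DS5-scale demo that runs in minutes |
| `mapped_fraction` | 0.58 | — | observed assigned-read fraction of a deep run |
| read length | log-normal, mean 483, `sdlog` 0.45 | bp | matches the reported mean length; spread chosen as a realistic cDNA length CV |
| quality law | normal(10, 3) truncated at 0 | Phred | straddles the Q = 7 cutoff so the filter is exercised (~84% pass) |
| `n_barcodes` | 0 (6 in multiplex tests) | — | six-way multiplexing mirrors the published design |

Strictly `mapped_fraction` is accepted in $(0, 1]$: the value 1 is
deliberately allowed so that count-level toys (where every read is
mapped) can be expressed, even though realistic configurations stay
below 1.

What the generator does **not** emulate: base-level error profiles,
isoform structure, length- or quality-dependent mappability, per-barcode
mapping-rate differences (one global `mapped_fraction`), and library
composition effects. Consequently a green test establishes that the
*statistical machinery* behaves as the sampling theory predicts on data
with the stated marginal structure — it does not reproduce any
data-specific magnitude from a real experiment (e.g. absolute detected
gene numbers), and the headline numbers of real runs are out of scope by
design.

# Numerical choices and conventions

* **Quality boundary**: reads at exactly the threshold are retained
  (discard is "strictly below"); the filter is idempotent.
* **Subset-size rounding**: half away from zero, everywhere
  (`subset_size()`, catalog coding counts).
* **Seed schedule**: replicate seed $=$ `base_seed`
  $+ 10007 \times$ fraction index $+$ replicate index — deterministic
  and collision-free for the default ladder; every random stage is
  scoped with `withr::with_seed()` so global RNG state is untouched.
* **Count-level subsampling** (`subsample_counts()`): a sequential
  conditional hypergeometric construction of the multivariate
  hypergeometric draw; it treats the supplied counts as the whole
  library, so it matches read-level subsampling in distribution when all
  reads are mapped (the regime of the equivalence test).
* **Degenerate inputs**: all-zero samples are errors for CPM; fewer than
  4 detected genes per class is an error for quartiles; empty pairings
  are errors for correlation; a header-only read table is an empty
  collection, not an error; malformed fields fail with a line number.
* **Config files**: flat-key JSON (`read_run_config()`); JSON was chosen
  over YAML to avoid a dependency outside the supported stack.

# Limitations

The %GEV conditioning on detection induces a small negative bias in the
median %GEV at low fractions (genes that survive detection in a shallow
replicate tend to be over-sampled there); this is a property of the
statistic, not of the implementation. Saturation is described
empirically — no species-accumulation model is fitted, and no
extrapolation beyond the reference depth is attempted. Differential
expression, isoform-level analysis and alignment are out of scope.
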