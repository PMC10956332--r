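---
title: "Methods: comparative genome architecture with genarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genome architecture with genarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genarch)
```

# The analysis

`genarch` implements the desk-side half of a comparative genome-architecture
study: from per-species genome annotations, repeat-masking tables and a
haploid-genome-size (C-value) database export, it asks which DNA components
— repeats, introns, exons — track genome-size variation across species, and
whether a focal taxonomic order (flatfishes, in the motivating use case) has
a significantly smaller genome than its relatives.

The pipeline stages are independent and composable:

1. `read_gff3()` → `build_gene_models()` → `feature_size_table()`:
   gene/exon/intron sizes per species.
2. `read_repeatmasker_out()` → `repeat_summary()`: repeat content per class.
3. `read_cvalue_table()` → `species_mean_cvalues()` →
   `compare_focal_order()` / `order_percentile_report()`: order-level
   genome-size statistics.
4. `genome_correlates()` / `assemble_report()`: the cross-species synthesis.

# Gene-feature sizes and the two conventions

Sizes are computed by coordinate differences on the 1-based, inclusive GFF3
coordinates, which are kept unchanged in memory; the convention switch is
applied only at size time, in one place, to avoid double-conversion bugs.

- **`difference` convention (default):** gene size = `end − start`; exon size =
  `end − start`; intron size = `next.start − prev.end`. These are the
  literal final-minus-initial coordinate differences.
- **`biological` convention:** `+1` on gene and exon sizes, `−1` on intron
  sizes — the actual base-pair lengths of the features and the gaps
  between them.

The two differ by exactly 1 bp per feature. The literal differences
undercount exon length and overcount intron length by 1 bp relative to the
standard length definition; published quantile tables produced with either
rule are therefore only comparable at the ±1 bp level, which is immaterial
for introns (medians in the hundreds of bp) but visible for the 1st
percentile of exon sizes. Both rules are first-class; every size function
takes `convention=`.

Three further rules close gaps the procedure itself does not specify:

- **Gene size uses the gene record's own coordinates** (the genomic locus),
  not the union of transcript extents. Annotation pipelines occasionally
  emit gene records wider than their transcripts; the locus is what the
  record asserts.
- **All transcripts contribute exons and introns**, with no
  canonical-transcript selection, so a 3-transcript gene contributes three
  (partially duplicated) exon sets. This makes the exon/intron arrays
  transcript-weighted; it is the only choice that needs no arbitrary
  selection rule.
- **Non-positive sizes are dropped and counted**, never fatal: real
  annotations contain zero-span records and overlapping exons, and a QC
  counter (`$dropped`, and the counters on `gene_models`) is more useful
  than an error 40 minutes into a 27-species run. Exons are sorted by start
  coordinate irrespective of strand before intron inference — sizes are
  strand-symmetric.

The invariant that anchors all of this is the **span identity**: for every
transcript, `sum(exon sizes) + sum(intron sizes)` equals the span of its
exon extent under either convention (span = `last end − first start`, plus
1 under `biological`). It is property-tested on random transcripts and
re-verified on 1000 synthetic transcripts by the acceptance script.

# Distribution summaries

- **Quantiles** use linear interpolation at position `1 + q(n − 1)` on the
  sorted sample (R's type 7, the default of most software stacks). No
  interpolation rule is universal; published quantiles computed under a
  different rule can differ by up to one inter-order-statistic gap, so
  cross-study comparisons of tail quantiles carry that caveat.
- **Spread** is reported as the 75th−25th interquantile difference (IQR);
  `sd` uses the n−1 denominator, and a single observation reports `sd = 0`
  with an explicit flag rather than `NA`.
- **Boxplot statistics** follow Tukey: whiskers at the most extreme data
  points within 1.5·IQR of the quartiles, everything outside is an outlier.
- **KDE** (`kde_log10()`) is a Gaussian kernel density of `log10(size)`
  evaluated on a uniform grid extended 3 bandwidths beyond the data range,
  normalized on the log10 axis. Typical settings for genome-scale data are
  bandwidth 0.1 with 1000 grid points for exons and 0.01 with 5000 points
  for introns — the narrow intron bandwidth resolves fine structure such
  as a shoulder near 1 kb in intron-expanded genomes. Plotting libraries
  disagree on whether a "bandwidth" argument is an absolute kernel sigma
  or a multiplier on a rule-of-thumb value; `bw_mode = "absolute"`
  (default) takes it as the sigma in log10 units, and
  `bw_mode = "scott-factor"` multiplies Scott's rule
  `sd(log10 x)·n^(−1/5)`. The ambiguity cannot be resolved from a plot, so
  both semantics are exposed.

# Repeat content

RepeatMasker class/family strings are collapsed to five classes by prefix:
`LINE*`, `SINE*`, `LTR*`, `DNA*`/`RC*` (rolling-circle transposons count as
DNA transposons), everything else `Other`. Two tallies are offered:

- **`raw` (default):** masked bp = sum of hit lengths
  (`end − start + 1`; RepeatMasker coordinates are 1-based inclusive),
  matching how RepeatMasker's own summary tables count.
- **`merged`:** per-class masked bp is the union length of that class's
  intervals (per sequence, via IRanges), and the overall total is the
  genome-wide union of all retained hits — the only definition under which
  "percent of genome masked" is guaranteed ≤ 100.

`pct_of_repeats` is always normalized by the per-class sum, so the five
class percentages sum to 100 whenever anything is masked; in `merged` mode
the overall total can be smaller than that sum when hits of different
classes overlap. Hits flagged `*` (overlapped by a higher-scoring hit) are
retained and marked, and the divergence filter (default: exclude hits more
than 20% diverged from consensus, the conventional `-div 20` masking
threshold) is applied at summary time, so both are reversible analysis
choices rather than parse-time losses. The summary also reports the four
mobile classes combined (`te_masked_bp`, `te_pct_genome`), so "TEs" can be
read either as DNA transposons alone or as all mobile elements.

# C-value statistics

C-values convert to physical size at **1 pg = 978 Mbp**. Duplicate database
entries per species are averaged (`species_mean_cvalues()`), with
conflicting taxonomy labels treated as an error naming the species rather
than silently resolved.

Order-level comparisons run each non-focal order against the focal order.
Genome-size data within orders are typically right-skewed and small-sample,
so the default test is the **Mann–Whitney U**, with a **Shapiro–Wilk gate**
(`normality_gate()`) available to justify the choice per sample: p < 0.05
routes to the non-parametric path; samples that cannot be tested (n < 3 or
constant) gate to non-parametric with a warning, and samples beyond the
test's n = 5000 limit are reduced to 5000 evenly spaced order statistics.
U is the number of pairs where the focal value exceeds the other-order
value, plus half the ties. The p-value is exact — full enumeration of rank
splits — when `n1·n2 ≤ 400` and the pooled sample is tie-free (exact
enumeration is sub-second there), else the normal approximation with tie
and continuity corrections; the computation is delegated to
`stats::wilcox.test` behind this contract, and the test suite checks it
against an independent brute-force enumeration. Welch's t
(`test = "welch"`) is offered because comparative studies sometimes report
t-tests on the same design; the two can disagree near the threshold, and
the output records which method produced each p-value. P-values are
unadjusted by default, matching how such order panels are usually
presented; `adjust = "holm"` is available. Significance stars follow the
conventional ladder: `*` < 0.05, `**` < 0.01, `***` < 0.001,
`****` < 0.0001.

`order_percentile_report()` answers the percentile-range question: global
cutoffs (e.g. the 5th and 10th percentile of all species' C-values), each
order's share of species at or below each lower cutoff, and within-order
percentiles for a named order.

**Spearman correlations** (`spearman_cor()`, `genome_correlates()`) are the
Pearson correlation of average-ranked data, with a two-sided p from the t
approximation on n−2 degrees of freedom — appropriate because genome size
relationships are monotone but not linear, and robust to the heavy upper
tail salmonid-scale genomes introduce. No phylogenetic correction is
applied (see Limitations).

# The synthetic-data model

The generators emulate the statistical structure of the real inputs, not
their content:

- **Annotations** (`gen_annotation()`): genes laid down sequentially and
  non-overlapping per sequence; per-gene exon count uniform on 2–12 by
  default; exon lengths log-normal with `meanlog = ln 130`, `sdlog = 0.5`
  (exon medians across fish species cluster tightly around 119–132 bp);
  intron lengths log-normal with `meanlog = ln 500`, `sdlog = 1.2` (a
  right-skewed, heavy-tailed distribution whose 99th percentile ≈ 8155 bp
  sits in the realistic several-kb range); intergenic gaps log-normal
  `ln 2000, 1.0`. The gap and exon-count defaults are field-realistic
  choices where no reference value exists; all are stylized, not fitted.
  Lengths are drawn as reals and ceiled to ≥ 1 bp; ground truth records
  every drawn size as a biological length, so the pipeline under the
  `biological` convention recovers them exactly — the round-trip is tested
  to identity.
- **Repeat tables** (`gen_repeatmasker()`): non-overlapping hits per class
  placed until the class's masked bp is within one mean hit length of its
  target percentage; divergence uniform on (0, 25) so the 20% filter has
  work to do; ground truth records per-class masked bp before and after
  that filter. Because hits never overlap, `raw` and `merged` tallies agree
  exactly on generated files.
- **C-value tables** (`gen_cvalues()`): per-order species values drawn
  log-normal (moment-matched to the requested mean and sd) or truncated
  normal; optional duplicate rows per species jittered with sd = sd_pg/10,
  so `sd_pg = 0` yields exact duplicates and exactly recoverable means.

One integer seed per spec drives a per-generator stream derived by a fixed
offset, so regenerating one input kind never perturbs another, and equal
seeds give byte-identical files.

What the generators deliberately do **not** emulate: nucleotide sequence,
UTR/CDS structure, alternative isoforms (every synthetic gene has one
mRNA), inter-gene and inter-species correlation, phylogenetic covariance,
and realistic RepeatMasker score/overlap structure. Passing tests therefore
demonstrate that the measurement machinery is correct on data with known
truth — they do not validate biological conclusions drawn from any
particular real dataset, nor reproduce any published per-species table,
since those depend on unversioned database snapshots.

# Numerical and scale choices

- Exact/approximate Mann–Whitney switch at `n1·n2 ≤ 400`, tie-free only.
- Quantile interpolation fixed to type 7 everywhere (tests, reports, KDE
  comparisons), so internal comparisons are never confounded by rule
  mixing.
- GFF3 parsing is strict: a wrong column count, non-numeric or inverted
  coordinates raise errors naming the offending line; attribute values are
  percent-decoded after comma-splitting so encoded commas survive.
  Write-then-read round-trips are tested to identity, and coordinates are
  cross-checked against an independent GFF3 reader.
- Output files are written atomically (temp file + rename); missing values
  serialize as `.`.
- Test and acceptance problem sizes: 1000 random transcripts for the span
  identity, 200 enumeration cases (n ≤ 8 per arm) for Mann–Whitney, 200
  null replicates × 4 comparisons at n = 15/order for the type-I check,
  5000 genes (~30 000 introns) for parameter recovery, 100 random interval
  sets on genomes up to 100 kb for the masking oracle, and 100 tied samples
  for the Spearman oracle. These sizes put Monte-Carlo noise well inside
  the asserted tolerances (e.g. the relative standard error of the
  recovered intron median at n ≈ 30 000 is ≈ 0.9%, against a 3% bound)
  while keeping the whole suite under a minute.

# Limitations

- Species are treated as independent: no phylogenetic generalized least
  squares or contrasts, so shared ancestry can inflate correlation
  significance.
- The per-species quantile tables of any published study are reproducible
  only given the same annotation release; the package reproduces the
  procedure, not the snapshot.
- The intron-size procedure infers introns purely from exon gaps within a
  transcript; trans-spliced or fragmented models produce "introns" that are
  assembly gaps, mitigated only by the non-positive-size filter and QC
  counters.
- `pct_of_repeats` treats the five classes as a partition; nested or
  cross-class overlapping annotations are counted per class, so the merged
  overall total is the honest bound on genome coverage.
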