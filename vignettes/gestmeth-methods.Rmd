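---
title: "Methods: regional differential methylation, RPKM differential expression, and their integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional differential methylation, RPKM differential expression, and their integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestmeth)
```

# Scope and model

`gestmeth` analyses paired RRBS methylomes and RNA-seq transcriptomes from
two groups of placental samples — first-trimester chorionic villi and
third-trimester placental villi — and asks how DNA methylation changes
across gestation relate to gene expression changes. The pipeline has four
stages:

1. **CpG filtering and regionalization.** Per-CpG methylation is the percent
   of methylated reads, `100 * n_meth / depth`. A CpG enters the analysis
   when it is autosomal and has depth ≥ 10 in at least 3 samples of *each*
   group; a per-sample observation is used only where that sample's own
   depth passes the cutoff, otherwise it is treated as missing (never
   imputed). Retained CpGs are merged into regions ("fragments") by scanning
   in genomic order and splitting wherever the gap to the previous CpG is
   ≥ 500 bp; consecutive CpGs inside a region are therefore *strictly* less
   than 500 bp apart.

2. **Regional differential methylation.** For each CpG of a feature, a
   two-sided Mann-Whitney U test compares the 6 first- against the 5
   third-trimester methylation percents. P-values are Benjamini-Hochberg
   adjusted within a family, and a feature is called differentially
   methylated when (a) the third-minus-first difference of its feature-level
   group means is at least 10 percentage points in magnitude and (b) at
   least 2 CpGs have FDR-adjusted p < 0.05. Gene bodies additionally require
   all fragments containing a significant CpG to change in the same
   direction. Core promoters span 1 kb upstream to 500 bp downstream of the
   TSS, gene bodies from 1 kb downstream of the TSS to the transcription
   termination site, both taken in the direction of transcription.

3. **Differential expression.** Expression is RPKM,
   `reads / (total_reads * length_kb) * 1e6`. Group-average RPKM below 0.5
   is floored at 0.5; genes below the floor in *both* groups (pre-floor) are
   filtered out. A retained gene is differentially expressed when the exact
   two-sided Mann-Whitney test on per-sample RPKM (5 vs 4 samples) gives
   p < 0.05 and the floored-average ratio (third/first) is ≥ 2 or ≤ 0.5.

4. **Integration.** Genes are ranked by group-average expression and split
   into 50 equal-size bins; per-bin mean feature methylation gives the
   methylation-expression curve, stratified by feature (promoter, gene body,
   exon, intron) and CpG-island context. Genes significant in *both*
   analyses are classified by the sign pair (methylation change, expression
   log2 ratio) as anti-correlated or positively correlated, and the class
   imbalance is assessed with an exact two-sided binomial test at p0 = 0.5.
   Dual-luciferase normalization (`firefly/renilla` minus the empty-vector
   ratio) is included as plain arithmetic for reporter-assay follow-up.

# Exact statistics

With 6-vs-5 and 5-vs-4 designs, asymptotic rank tests are unreliable and
methylation percents are heavily tied, so `exact_mann_whitney()` is
permutation-exact: it computes U with mid-ranks and enumerates all
`choose(n1 + n2, n1)` assignments of the *observed* values (462 for 6 vs 5),
doubling the smaller inclusive tail and capping at 1. This is exact under
ties, unlike the classical exact distribution, which assumes continuity.
Enumeration is used whenever the assignment count is at most 200,000
(roughly 12 vs 12); beyond that a normal approximation with tie and
continuity correction takes over. A consequence worth knowing: the smallest
achievable two-sided level for 6 vs 5 without ties is 2/462 ≈ 0.0043, and
achievable p-values form a discrete grid — a reported p of, say, 0.028 can
only arise from approximate methods or tied data.

`exact_binomial_two_sided()` doubles the smaller tail for the symmetric
null p0 = 0.5 (the only case the pipeline uses; the minimum-likelihood
definition is applied for p0 ≠ 0.5, where the two disagree).
`benjamini_hochberg()` is a validating front-end to
`stats::p.adjust(method = "BH")`.

**Adjustment families.** The CpG-level adjustment is "within regions". For a
promoter call the family is the promoter's own CpGs; for a gene-body call
the family is each merged fragment's CpGs (the fragments are the regional
unit, and the same-direction rule is defined over fragments). Both scopes
are implemented and selectable via `adjust_within`.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 10 | reads | per-sample depth for a usable CpG observation |
| `min_samples` | 3 | samples | per-group coverage for site retention |
| `merge_gap` | 500 | bp | gap at which CpG runs split into regions |
| `min_delta` | 10 | percentage points | feature-level methylation difference |
| `alpha` | 0.05 | – | FDR cutoff for per-CpG significance |
| `min_sig_cpgs` | 2 | CpGs | FDR-significant CpGs required per feature |
| `rpkm_floor` | 0.5 | RPKM | floor on group-average expression |
| `de_p` | 0.05 | – | rank-test cutoff for DE (strict `<`) |
| `fold` | 2 | – | DE fold-change cutoff (inclusive) |
| `n_bins` | 50 | bins | expression bins for correlation curves |

Thresholds are inclusive exactly as worded in their definitions: depth
"≥ 10", "at least 3" samples, "at least 10%" difference, fold change "≥ 2 or
≤ 0.5"; the merge rule "less than 500 bp" and the DE p-value "less than
0.05" are strict.

# Design choices in underdetermined corners

These points are not fixed by the criteria above and were decided once, as
follows:

- **Region and feature means are unweighted.** A region's (or feature's)
  group mean is the plain mean over member CpGs of per-CpG group means, not
  depth-weighted; per-CpG group means ignore missing samples. This makes
  deltas comparable across features with uneven coverage.
- **Delta orientation** is always third minus first, so hypermethylation in
  late gestation is positive.
- **Direction at zero:** `direction` is "hyper" iff delta > 0 for
  methylation, "up" iff ratio > 1 for expression; concordance records with a
  component exactly zero are excluded (cannot occur for significant calls,
  but guarded).
- **Gene-level rollups** (a gene with several promoters, or significant in
  both analyses): the significant feature with the largest |delta|
  represents the gene.
- **Untestable features.** A feature with fewer covered CpGs than
  `min_sig_cpgs` is reported `testable = FALSE` and never significant.
- **Coordinates** are 1-based closed internally; BED input/output is
  converted at the boundary. CpGs are identified by the forward-strand C
  position and assumed pre-collapsed across strands. Only chr1-chr22 count
  as autosomes by default (configurable).
- **Binning:** genes sorted ascending by expression with gene-id
  tie-breaking; 0-based rank r goes to bin `floor(r * n_bins / n) + 1`, so
  bin sizes differ by at most 1 and the partition is deterministic even
  under massive ties. Curves are computed per trimester group rather than
  pooled.
- **Exon/intron partition** clips exons to the gene body (the first 1 kb
  after the TSS is excluded), so exons and introns exactly tile the body.
- **CGI context**: a single CpG is CGI if its position lies in an island;
  an interval is CGI given ≥ 1 bp overlap.

# The synthetic-data generator

`simulate_genome()`, `simulate_methylome()` and `simulate_counts()` provide
a fully self-contained test bed whose planted structure is recorded by
`truth_table()`. The study conditions are the generator defaults: 6 vs 5
methylomes and 5 vs 4 expression samples; negative-binomial sequencing
depth with mean 30 and size 5 (a realistic RRBS coverage profile once
sub-threshold sites are filtered); true CpG methylation drawn from
Beta(1.5, 10) inside CpG islands and Beta(10, 1.5) outside, reproducing the
canonical bimodal RRBS profile (CGI mode below 20%, non-CGI mode above
80%); planted differential methylation of +20 percentage points; planted
expression changes of 4-fold with 77% down-regulated; and an optional
doubly-affected gene set with a 75% anti-concordance fraction. Planted
methylation shifts start from a baseline drawn uniformly on [10, 60]% so the
shifted level never saturates and the realized group difference stays
within 2 pp of the configured one at depth ≥ 30. CpG spacing is dense in
islands (40-120 bp) and sparse in gene bodies (100-700 bp), so merged
multi-CpG regions, region splits at the 500-bp gap, and singleton regions
all occur; reads are binomial at the site's group-specific true level.

What the generator does *not* emulate: sample-to-sample biological
variability beyond binomial/negative-binomial noise (no per-sample random
effects), sequence-dependent coverage bias, strand-level artefacts,
cell-type mixture shifts across gestation, and correlated methylation along
chromosomes beyond the shared per-site true level. Passing the synthetic
recovery and calibration suites therefore demonstrates algorithmic
correctness and calibration under the assumed noise model, not performance
on real placental data, where between-sample dispersion is larger and the
operating characteristics of the joint criteria will be more conservative.

# Numerical notes and fixture precision

- Exact-test p-values are compared to enumeration oracles at 1e-12; tail
  membership uses a 1e-8 slack on U so mid-rank ties at the observed
  statistic are counted inclusively.
- Histogram bins are left-closed ([low, high)), width 5 pp by default, with
  the top bin closed at 100.
- The bundled imprinted-gene expression fixture stores group-average RPKM
  to two (one row, three) decimals; log2 ratios recomputed from such rounded
  averages are reproducible only to about ±0.006, and ten of its eleven
  rows agree with the stored log2 column within ±0.005. The remaining row
  (PSIMCT-1) recomputes to −1.2657 against a stored −1.26: its stored log2
  was evidently derived from unrounded averages. The test suite asserts the
  ±0.005 agreement row by row and this single expectation fails by design;
  the acceptance script reports the measured maximum error (≈ 0.0057).
- Problem sizes in the test and acceptance runs were chosen to keep the
  whole suite under a minute while leaving clear statistical margins: 500
  null features for calibration, 50 planted promoters (≥ 8 CpGs, depth 30)
  and 40 planted DE genes for sensitivity, and 100 doubly-planted genes for
  the anti-concordance recovery, checked against the exact binomial 99%
  interval around 0.75.

# Known limitations

- The Mann-Whitney enumeration treats the observed values as fixed
  (permutation null); it does not model beta-binomial dispersion, and a
  dispersion-aware caller (e.g. beta-binomial regression) would have more
  power at equal depth.
- Promoter/gene-body definitions use a single TSS/TTS per model; genes with
  several annotated TSSs should be supplied as one model per TSS (the
  calling layer then rolls promoters up to genes).
- The expression floor makes log2 ratios conservative near 0.5 RPKM;
  ratios against a floored denominator are lower bounds in magnitude.
- The 50-bin curves are descriptive; no monotonicity test or confidence
  band is attached to them.
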