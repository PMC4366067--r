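---
title: "Dosage-response analysis of allopolyploid transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-response analysis of allopolyploid transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidosage)
```

## The problem

Allopolyploids carry genome sets from two divergent parental species, often
in odd copy numbers. In the Iberian cyprinid *Squalius alburnoides* complex,
triploid PAA hybrids (one *S. pyrenaicus* P haplome, two *Anaecypris
hispanica*-like A haplomes) coexist with diploid PA hybrids and the
parental-like diploids AA and PP. The central quantitative question is how a
triploid genome is expressed relative to its diploid counterpart: strictly
in proportion to gene dosage (a PAA/PA ratio of 1.5), compensated back to
the diploid level (ratio 1), or something in between.

`ploidosage` implements this comparison as a reusable pipeline over
per-library abundance tables (FPKM/RPKM) and genome-normalized qPCR plate
data, with a synthetic-data generator providing ground-truthed inputs for
every stage.

## Ratio profiling

For each gene shared between two libraries, the fold change is the
numerator FPKM over the denominator FPKM; the profile is summarized by the
ordered log2 ratios, their sign counts and their median. The balance of
lower vs higher expressed transcripts is tested with a one-degree-of-freedom
chi-square against a 50:50 split (no continuity correction — at transcriptome
scale the correction is irrelevant, and the uncorrected statistic is the
classical one), and two comparisons are contrasted with the uncorrected 2x2
contingency chi-square.

**Zero abundances.** A fold change is undefined when either library reports
zero. The default policy excludes such genes and reports how many were
dropped; this keeps fold changes finite without inventing a pseudocount
magnitude. A pseudocount policy (both abundances incremented before
division, default 0.5 FPKM) is available for analyses that must retain
presence/absence genes.

**Median convention.** For even profile lengths the median is the mean of
the two central order statistics.

## Similar expression and dosage classes

A gene is *similarly expressed* (SE) when `|log2(fold change)| < 1`
(strict): less than twofold in either direction. SE genes are partitioned
into dosage-response classes at fold changes 0.75, 1.25 and 1.75:

| class | interval      | reading                                    |
|-------|---------------|--------------------------------------------|
| I     | [0.75, 1.25]  | compensated (ratio about 1)                |
| II    | (1.25, 1.75]  | dosage sensitive (ratio about 1.5)         |
| III   | below 0.75    | repressed beyond compensation              |
| IV    | above 1.75    | overexpressed beyond dosage                |

The published class definitions use open intervals, leaving the boundary
points unassigned — a measure-zero set for continuous data but a real one
for rounded inputs. We close class I and half-open class II so that a
boundary tie receives the more conservative compensated or dosage-sensitive
label; the bounds are configurable through `analysis_config()`.

Reported percentages are rounded half away from zero (commercial rounding),
to integers for class shares and to one decimal for the DE share of all
genes, matching how such tables are conventionally printed.

## Differential expression and the dependent-test FDR

With a single library per genomotype there is no biological replication, so
dispersion cannot be estimated. The DE engine is therefore a deliberately
simple two-library exact binomial test: conditional on a gene's total count,
fragments fall into library A with probability
`libsize_a / (libsize_a + libsize_b)` under the null, and the two-sided
p-value sums all outcomes no more likely than the one observed. This is a
documented stand-in where a replicated design would call for a
negative-binomial framework; absolute DE counts from it are not comparable
with those from such frameworks, and the package makes no such claim.

Raw p-values are adjusted with the Benjamini–Yekutieli step-up — the
standard procedure valid under arbitrary dependence among tests, which is
what "FDR correction for dependent tests" denotes; it inflates the
Benjamini–Hochberg q-values by the harmonic factor `c(m) = sum(1/k)`.
Significance is `q <= 0.05`. SE and DE are computed independently: a deeply
sequenced gene at 1.9-fold can be both.

## Additivity

The mid-parent expectation assigns each haplome copy half of the matching
parental diploid's expression: `PP/2 + AA/2` for PA and `PP/2 + AA` for
PAA, generalized as `(copies_P * PP + copies_A * AA) / 2` so that the
degenerate cases PP and AA reduce to the parent itself. A gene is
additively expressed when `-1 < log2(observed/expected) < 1` (strict);
outside that window it is below- or above-additive. When either value is
zero the log ratio is infinite and the gene is categorized `undefined` and
excluded from percentage summaries — any finite assignment would be
arbitrary. The balance of the two non-additive categories is tested with
the same 50:50 chi-square as the ratio profiles.

## Relative transcriptome size

FPKM ratios compare expression *per transcriptome*; if the two
transcriptomes differ in total size, per-cell conclusions drawn from them
are confounded. The size of the PAA transcriptome relative to PA is
estimated per target gene by combining two measurements:

1. **Transcripts per genome** — qPCR on co-extracted cDNA and gDNA. Each
   target's cDNA Cq is normalized per sample against the arithmetic mean of
   the three gDNA-specific reference Cqs (`rpl8`, `eef1a`, `actb2`); on the
   Cq scale this is exactly the geometric-mean normalization of the linear
   quantities under efficiency-2 amplification, which is assumed throughout
   (the pure Livak method; no per-target efficiency calibration). The
   PAA/PA ratio is `2^-ddCq` with the ddCq taken between genomotype means
   of the per-sample dCq values; per-sample ratios are retained only for
   the SD.
2. **Transcripts per cell** — the per-genome ratio times the ploidy
   quotient 3/2, because each PAA cell carries three genome copies per two
   in PA.
3. **Size** — transcripts per cell divided by the gene's transcripts per
   transcriptome (FPKM) ratio from the RNA-seq libraries.

Each of the six panel genes yields an independent size estimate; the
aggregate reports their mean and SD, two-sided one-sample t-tests against
1.5 (genome-wide dosage effect) and 1.0 (genome-wide compensation), and a
Tukey-fence outlier screen (1.5 IQR beyond the hinge quartiles, hinges as
in `stats::fivenum()`). Sidedness is not specified in this field's
convention for these tests; we use two-sided throughout.

```{r size-example}
pub <- published_liver_ratios()
tab <- size_table_from_ratios(pub$gene, pub$per_genome, pub$per_transcriptome)
tab
round_half_away(mean(tab$size), 1)
one_sample_t(pub$size_published, 1.5)$p_two_sided
```

A note on the shipped panel: three of the six published rows are not
internally consistent at the printed one-decimal precision (their per-cell
column is not 1.5x the per-genome column as printed), which indicates the
original arithmetic was done on unrounded intermediates. The package
recomputes from the per-genome column and documents the discrepancy rather
than reproducing it.

## The synthetic-data generator

`simulate_expression()` emulates the study layout — one RNA-seq library per
genomotype for PP, AA, PA and PAA — with known per-gene truth:

- AA abundances are log-normal (`baseline_log_mean = 2`,
  `baseline_log_sd = 1.5` on the natural-log scale: median about 7 FPKM
  with a realistic four-orders-of-magnitude dynamic range);
- PP is AA shifted by a Normal log2 divergence (`sd = 1`, a substantial
  between-species difference);
- PA is the exact mid-parent; PAA is the exact additivity expectation for
  a configurable fraction of genes (default 0.36, the magnitude observed
  for triploid hybrid livers) and otherwise PA times a true fold change
  drawn uniformly inside the assigned dosage-class interval, with the
  class mixture defaulting to the published SE composition
  (I 0.45, II 0.17, III 0.34, IV 0.04);
- log2-normal measurement noise (default sd 0.2) is applied last,
  independently per gene and library;
- integer fragment counts are derived from the noisy abundances by
  inverse-FPKM rounding against the configured library sizes (default
  2e7 fragments per library). The stored abundance keeps the exact
  continuous value: the count is a quantized view of it, so count-implied
  FPKM and stored FPKM agree only to within half a fragment. The ratio
  stages consume the abundance; the DE stage consumes the counts.

`simulate_qpcr()` emulates the plate design (five biological by three
technical replicates per genomotype, six cDNA targets, three gDNA
references): a per-sample template-input offset shifts every well and
cancels in the normalization, reference wells sit at target-specific
baselines, target wells are placed so that the expected `2^-ddCq` equals
the configured true per-genome ratio, and Gaussian Cq noise (default sd
0.15 cycles, a typical technical-replicate spread) is added per well.
Generation is fully reproducible from the seed.

**What the generator does not emulate.** Real data bring mappability and
annotation artifacts, GC and length biases, shared-assembly correlation
between genomotypes, biological replication structure, and qPCR efficiency
differences between targets. Passing recovery tests on synthetic data
therefore demonstrates the correctness of the arithmetic and the
identifiability of the design, not robustness to those artifacts.

Two structural consequences of the noise model are worth knowing. First,
near a class boundary, measurement noise moves genes across it
asymmetrically (the classes have different widths and occupancies), so
noisy class tallies are biased relative to the generating mixture beyond
plain binomial sampling error — the bias is a property of hard thresholds
under noise, not of the implementation, and vanishes with the noise.
Second, all targets on a plate share the same three gDNA reference wells,
so per-gene size estimates are positively correlated; the aggregate t-test
treats them as independent (as the field's standard analysis does) and is
accordingly anti-conservative under the null.

## Problem sizes and numerical choices

The test suite exercises the classifier at 20000 genes and the qPCR
recovery at 200 simulated plates, sizes chosen to give stable empirical
fractions while keeping a full run in well under a minute. Fold-change
comparisons use strict inequalities at thresholds; degenerate one-sample
t inputs (numerically constant vectors) are resolved exactly rather than
erroring; the exact binomial test guards probability ties with a 1e-12
relative tolerance; FPKM arithmetic is done in double precision (32-bit
integer products overflow at transcriptome scale).

## Limitations

- No read-level processing: the pipeline starts at abundance tables.
- The DE engine is the unreplicated-design stand-in described above.
- Amplification efficiency is fixed at 2; efficiency-calibrated variants
  of the Livak method are out of scope.
- Gene identifiers are opaque; cross-reference-system joins are the
  caller's responsibility and deliberately unsupported.
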