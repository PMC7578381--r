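---
title: "Methods: integrative methylation–expression analysis in paired tumor/normal designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylation–expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methex)
```

# The analysis model

`methex` implements a complete chain from raw 450K-style probe
intensities to epigenetically dysregulated gene sets and TF rankings in
a *paired* design: each patient contributes one tumor and one adjacent
normal sample, and every test in the pipeline is a paired test. The
statistical backbone is deliberately nonparametric — the Wilcoxon
signed-rank test on per-pair differences — because per-probe β values
are bounded, often bimodal, and heteroskedastic, which makes Gaussian
per-probe models fragile at cohort sizes of 10–20 pairs. A paired
t-test on logit-scale β (M-value-like) is available as a configuration
alternative (`dmp_method = "t_logit"`) for users who prefer a
moment-based test.

## Beta values

Methylation is summarised as
$$\beta = \frac{M}{M + U + 100},$$
with $M$ and $U$ the methylated and unmethylated channel intensities.
The +100 offset regularises low-intensity probes and bounds β strictly
below 1; `compute_beta()` enforces non-negative inputs and reproduces
the formula exactly (no clipping, no recalibration).

## Quality control

Filters run in a fixed order, and order matters: samples are dropped
first (≥ 25% of probes at detection p ≥ 0.01 — both comparisons
inclusive, exactly as specified), and the probe-level detection rule
(failing in ≥ 50% of samples) is then evaluated over the *remaining*
samples, since the failing fraction depends on the denominator. Probe
rules are evaluated in the order detection → NA-masked → SNP (MAF
strictly > 0.01 within 10 bp) → non-CpG → sex chromosome, and the first
matching rule is recorded for each removal, so QC reports are
deterministic and auditable.

Mislabelled pairs are detected rather than curated visually: the 1,000
most variable probes (variance of β across retained samples; MAD is a
possible alternative but variance is the simplest reading and is what
we fix), 1 − Pearson correlation distance, average-linkage clustering
cut at $k = 2$ — two clusters because tissue has two classes. A sample
is flagged when its recorded tissue label disagrees with its cluster's
majority label; a patient is flagged when either member of the pair is
flagged. Removal is a configuration choice (`remove_flagged`, default
TRUE) and always removes the whole pair, keeping the design paired.
Degenerate inputs (all-identical β, majority ties within a cluster)
flag nothing and warn.

## Normalization

Two steps, in an order the package fixes explicitly: the SWAN-style
within-array correction operates on *intensities* (it is defined on
them), β is computed from the adjusted intensities, and quantile
normalization operates on *β* across samples — discovery and
validation cohorts separately by default (`qn_per_cohort`), since the
cohorts were processed independently and joint normalization would leak
information between them.

The within-array step stratifies probes by the number of CpGs under the
probe (1, 2, ≥ 3 — counts above 3 are pooled), draws equal-size seeded
random subsets of type-I and type-II probes per stratum, and averages
the two pooled subsets' empirical quantile functions into a reference;
each design type's probes are then mapped onto that reference by
monotone interpolation through the type's own subset quantiles
(`approx`, clamped at the subset range). Building the reference over
the *pooled* subset rather than per stratum makes the per-type map
globally monotone, which is what guarantees the within-type
rank-preservation property the tests assert. Strata with fewer than two
probes of either type are skipped with a warning. The subset draw is
the only randomness in the whole analysis chain and is governed by one
seed, logged in the provenance.

Quantile normalization replaces each value by the across-sample mean of
its rank's order statistics; tied values receive the mean of their tie
run's reference values. Consequently sorted columns are identical
across samples *except* within tie runs — the test suite checks exact
identity at tie-free positions and bounds the tie-averaging deviation.

## Differential methylation

Per probe: paired Wilcoxon signed-rank across complete pairs (exact
null distribution when the number of non-zero differences is ≤ 25,
normal approximation with continuity correction above), BH correction
across all tested probes, and the joint call rule q < 0.05 with
|Δβ| ≥ 0.2, where Δβ is the difference of per-tissue means over paired
samples only. Probes with all-zero paired differences get p = 1 by
convention. The calling is label-symmetric: exchanging tissue labels
negates Δβ and swaps hyper ↔ hypo at identical p-values (a property
test).

Regions are gene-centric: manifest sub-regions collapse to promoter
(TSS1500, TSS200, 5′UTR), body (1stExon, Body) and 3′UTR, with
multi-mapping preserved. A region is a DMR when at least 25% of its
mapped probes (denominator: *all* probes mapped to the region after
filtering, not DMPs — the fraction must be defined for regions with no
DMPs) are DMPs of one direction while the opposite direction stays
below 25%; regions crossing 25% in both directions are recorded as
`ambiguous` and excluded from the DMR list rather than silently
dropped, since "unidirectional" excludes mixed regions. Region
methylation level is the mean β of the region's DMPs per tissue.

The verification route is intentionally different machinery over the
same data: each region is summarised per sample by its mean β over all
region probes, the region means get the paired Wilcoxon + BH treatment,
and `verification_overlap()` reports the fraction of primary DMRs
verified in the same direction. On the default synthetic conditions the
overlap is essentially complete; on real data it quantifies the
agreement between probe-level and region-level views.

Patient stratification clusters the per-patient promoter methylation
change (tumor β − paired normal β, averaged over a gene's promoter
DMPs) with Euclidean average-linkage at $k = 2$, recursively splitting
the larger cluster; final clusters are ordered severe → mild by mean
|change|.

## Expression and integration

The expression stage is a stand-in for an aligner/assembler
differential-expression pipeline and operates on a gene-level FPKM
matrix: paired Wilcoxon on log2(FPKM + 1), BH, and a pseudocount-shrunk
fold change log2((mean_T + 1)/(mean_N + 1)). There is no fold-change
floor by default and "expressed" means FPKM strictly above 0.1 — both
configurable, both stated because the upstream convention does not pin
them. A precomputed external DE table (gene, log2_fc, p, q) can be
substituted wholesale.

Integration is a set intersection by definition: silenced = promoter
hyper ∧ expression down; overexpressed = promoter hypo ∧ expression up;
ambiguous promoters never classify. The Spearman filter computes, per
gene, the rank correlation between per-sample mean promoter-DMP β and
per-sample log2(FPKM + 1) over *all* paired samples (tumor and normal,
n = 2 × pairs) — using both tissues maximises dynamic range and is the
default; a tumor-only mode exists. The p-value is exact (full
permutation enumeration) for n ≤ 9 and the t-approximation above;
ties receive average ranks; zero-variance inputs yield an undefined ρ
and a FALSE flag. The flag applies ρ < −0.5 with *raw* p < 0.05 — no
multiplicity correction, mirroring the double-threshold convention this
filter comes from.

## Enrichment and TF networks

Gene-set enrichment uses the two-sided hypergeometric test in its
doubled-smaller-tail form, min(1, 2·min(P[X ≥ k], P[X ≤ k])), with
"Bonferroni step-down" resolved to the Holm procedure — the standard
reading of that phrase. Term redundancy is grouped by pairwise Cohen's
kappa between significant terms' overlap-gene memberships, computed
over the union of significant terms' overlap genes (term–term
similarity is about their associated genes, not the genome;
configurable); terms join a group when κ ≥ 0.4 and groups are graph
connected components — the simplest faithful reading of iterative
group merging, with a deterministic leader rule (lowest corrected p,
then larger overlap, then lexicographic id).

The TF network is a direct construction: a directed edge from a TF to
each of its library targets present in the query list (edges to query
genes that are themselves TFs included), out-degree = edge count,
ranked descending with lexicographic tie-break. TFs appearing in the
query are flagged as epigenetically regulated.

# The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions. Defaults: 14 tumor/normal pairs plus 10 unpaired validation
tumors; 6,000 probes over 300 genes (1–3 probes per gene per
sub-region); planted β shift 0.3 at ~5%/3% hyper/hypo prevalence;
within-group β noise on the logit scale with sd 0.25 (≈ 0.05 on the β
scale at mid-range β, where the logit derivative is ~4); 40 silenced
and 60 overexpressed genes with 4-fold expression effects and log2
noise sd 0.3; per-rule QC plants of 50/30/20/10/40 probes; 2
label-swapped pairs; multiplicative type-II intensity bias 1.5; a
93-set TF library whose three hubs target 81/53/48 of the planted
epigenetically regulated genes (the first and third hubs are themselves
planted genes). These sizes were chosen as a desk-scale cohort a
two-group 450K study would resemble while keeping a full pipeline run
in seconds; the replicate analyses in the test suite and acceptance
script use five seeds of this configuration.

Design choices worth knowing:

* β is planted in β space and noise is added on the logit scale, then
  converted to (M, U) pairs by drawing a total intensity
  (log-normal, median 4,000, floored) and solving M = β(M + U + 100) —
  so the *pipeline*, not the generator, applies the β formula, and at
  zero noise the planted Δβ is recovered to machine precision.
* Detection p-values are Uniform(0, 0.005) for passing measurements
  and Uniform(0.01, 1) for planted failures, making the ≥ 0.01 rule a
  crisp oracle. Planted QC sets are pairwise disjoint by construction.
* The type-II bias multiplies both channels, shifting type-II
  intensity distributions (what the within-array correction targets)
  while barely perturbing β — so intensity-level bias and β-level
  effects can be validated independently.
* Label swaps exchange tissue labels in the sample sheet only; the
  data columns are untouched, exactly the error mode the clustering QC
  is meant to catch.
* For planted genes, a per-gene-per-sample latent factor couples
  promoter β (positively) and log2 expression (negatively), giving the
  Spearman filter true positives beyond the tumor/normal group
  separation itself.

What it does **not** emulate: batch or chip effects, background
fluorescence and dye bias, probe cross-hybridisation, cell-type
composition, copy-number interference with intensities, count-level
expression noise, or annotation errors. Passing the planted-truth tests
therefore demonstrates that the *logic* of every stage is correct at
realistic effect sizes and noise — not that the pipeline is robust to
every artefact of real arrays; the QC and normalization stages address
the artefact classes they model (detection failures, design-type bias,
label swaps) and no others.

# Numerical conventions

* Thresholds are applied exactly as printed: inclusive ≥ for detection
  p (0.01), sample fraction (25%), probe fraction (50%), |Δβ| (0.2) and
  the DMR fraction (25%) and kappa (0.4); strict > for SNP MAF (0.01)
  and the FPKM expression floor; strict < for q-values, ρ (−0.5) and
  the correlation p (0.05).
* All-zero paired differences ⇒ p = 1; zero-variance correlation
  inputs ⇒ ρ undefined, flag FALSE; empty queries and empty DMP sets
  propagate as empty-but-valid tables through the pipeline.
* Ties: average ranks everywhere (Spearman, quantile normalization);
  ranking tie-breaks are lexicographic; group-leader ties break by
  overlap size then id.
* Determinism: one seed drives the generator, one the normalization
  subsets; both are recorded, and pipeline manifests carry md5
  checksums of every output.

# Known limitations

* The per-probe test at 10–20 pairs has a granular exact null; the
  minimum attainable p is 2/2^n, which bounds achievable q-values when
  few probes are tested.
* Gene-region DMR calling does not detect regions that lack gene
  annotation (no bump-hunting / sliding windows) — by design.
* The expression stage does not model counts; users with raw reads
  should run their preferred DE pipeline and supply its output table.
* Enrichment depends entirely on user-supplied GMT libraries; none are
  bundled.
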