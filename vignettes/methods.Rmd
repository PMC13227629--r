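---
title: "Methods: models, rules and design choices in rettomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in rettomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
pipeline, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The study layout and the seven contrasts

Every analysis is stratified over a 2-genotype design — the MECP2-mutant
line (RTT) against its isogenic control (IC) — crossed with a
region-by-time layout: undifferentiated iPSCs at day 0, and dorsal and
ventral forebrain organoids at days 13, 40 and 75, with replicate cultures
per cell. Because the day-0 iPSC cultures precede regional specification,
the day-0 comparison is one shared contrast, giving seven canonical
RTT-vs-IC contrasts: `D0`, `D13-dorsal`, `D13-ventral`, `D40-dorsal`,
`D40-ventral`, `D75-dorsal`, `D75-ventral`. All "at least *k* of 7"
decision rules (markers, GSEA aggregation, isoform usage, allele-specific
expression) count `D0` once. `enumerate_contrasts()` orders contrasts by
day with dorsal before ventral and drops — with a warning — any stratum
lacking a genotype.

## Preprocessing

**RNA.** Genes are kept when their counts-per-million exceed 10 in at least
3 samples; CPM is computed on raw library sizes, before scale-factor
estimation (whether the original filter used pre- or post-normalization CPM
is not determinable; the pre-normalization choice is fixed here and
documented). X-chromosomal genes are removed *before* normalization because
the active X differs between the RTT and IC lines. Scale factors use the
trimmed mean of M-values with the canonical parameters — log-ratio trim
0.30, abundance trim 0.05, reference column the sample whose
75th-percentile CPM is closest to the mean — and log2-CPM uses effective
library sizes with a library-size-scaled prior count of 2 (configurable).
The implementation matches the established edgeR implementation to 1e-6 on
test fixtures.

**Protein.** Sex-chromosome proteins are removed, then proteins must be
quantified in at least two replicates of at least one experimental group
(genotype x region x day). The variance stabilizer is a deliberate,
documented stand-in for full maximum-likelihood VSN: per-sample affine
calibration on the log scale (median/MAD alignment to a feature-median
pseudo-reference) followed by a generalized log,
`glog2(y) = log2((y + sqrt(y^2 + a^2))/2)`, with offset `a` the 5th
percentile of calibrated intensities. It shares VSN's contract —
calibration plus a transform that is linear near zero and logarithmic for
large values — while being deterministic and dependency-light. Calibration
is done on the log scale because affine alignment of raw intensities
spanning several orders of magnitude is not monotone and would scramble
ranks.

**Missingness.** A protein missing in *all* replicates of at least one
group is classified MNAR (left-censored by the detection limit); any other
missing pattern is MAR; otherwise complete. MAR cells are imputed by
k-nearest-neighbour averaging over protein profiles (k = 10); MNAR cells
are drawn from the left tail of a normal centred at the host sample's 1st
percentile with the sample's MAD as scale, truncated above at that
percentile — values plausible below the detection limit. The MNAR draw is
the only stochastic step in preprocessing and takes an explicit seed
(default 0). Observed cells are never altered.

## Differential analysis and markers

One moderated linear-model engine serves both omics layers (log2-CPM for
RNA, imputed log2 intensities for protein): per feature, a two-group fit
with empirical-Bayes variance moderation — the prior variance and prior
degrees of freedom are pooled across all features via `limma::squeezeVar`
— and a two-sided moderated-t P value, with Benjamini–Hochberg FDR within
the contrast. Setting `prior_df = 0` recovers the ordinary equal-variance
t-test exactly, which the tests exploit as an oracle. The count-specific
quasi-likelihood machinery is intentionally not reproduced; the contract is
the per-contrast (log2FC, P, FDR) triple, and the engine's null calibration
is verified by simulation (fraction of nominal P < 0.05 within 0.05 ± 0.02
over 20 seeds).

A feature is *differentially expressed* at FDR < 0.05 and |log2FC| > 1,
both strict, as printed. The ranking score fed to GSEA is
`-log10(P) * sgn(log2FC)`, with P capped at the double-precision floor
(with a warning) and score 0 when the fold change is 0.

Marker selection is a declarative rule grammar (`marker_rule()`): a set of
contrasts that must be significant (with FDR and |log2FC| thresholds), a
set that must look null (nominal P floor), a direction-consistency flag and
a minimum significant-contrast count. Two rules are built in: `overall`
(differentially expressed with one direction of effect in at least six of
the seven contrasts) and `transient_d13` (differential at both day-13
contrasts, nominal P > 0.1 at every day-40 and day-75 contrast). The full
selection-criteria table of the original analysis is not published in the
main text, so additional rules are supplied by the user rather than
hard-coded.

## Enrichment

`preranked_gsea()` computes the weighted Kolmogorov–Smirnov running-sum
enrichment score (weight 1 on |score|, the canonical preranked choice) on
the ranked list, ties broken by feature id. The null permutes gene labels —
hit positions are redrawn uniformly — rather than phenotypes, matching the
permutation logic used throughout the pipeline; NES divides ES by the mean
|null ES| of the same sign, the nominal P is the one-sided same-sign
permutation tail with the +1 correction, and FDR is BH across sets.
Set-size bounds (10–500) and the permutation count are configurable since
the original tooling's internals are not specified.

Terms significant (FDR < 0.05) in at least 4 of the 7 contrasts are
aggregated. Redundancy reduction replaces ontology-graph semantic
similarity with **gene-overlap Jaccard clustering**: edges where
J = |A∩B|/|A∪B| ≥ 0.5, connected-component clusters, and as representative
the member with the highest mean −log10 P across contrasts — the same
representative rule, with the overlap semantics of the original figure,
but no ontology dependency. The threshold is configurable.

`permutation_count_null()` answers "how many significant terms would random
orderings give": each outer permutation assigns uniform random scores to
the universe, reruns GSEA, and counts significant sets; the reported
probability is `(1 + #[null ≥ observed]) / (n_perm + 1)`. Inner and outer
permutation counts trade accuracy for time and are exposed as parameters.

Eigengenes are PC1 of a term's member-gene submatrix (members standardized
across samples), oriented to correlate positively with the mean member
profile (an arbitrary-sign convention made deterministic; when the mean
profile is flat the orientation is left as computed). Module membership is
the absolute Pearson correlation with the eigengene; explained variance is
the PC1 share.

## Trajectory

The reference trajectory is fitted on IC samples only, restricted to a
developmental gene set (in the organoid study, the forebrain-development
ontology term; in the synthetic bundle, the generator's high-loading axis
genes). Choices where the original description is silent, fixed here and
configurable: 2 principal components retained; one cubic smoothing spline
per component against the day-ordered sample rank, smoothing chosen by
generalized cross-validation (or a fixed `spar`); evaluation on a dense
grid of 400 points (≥200 enforced); pseudotime is cumulative arc length
along the resulting polyline, with the origin at the earliest-day end and
orientation flipped if pseudotime decreases with day. Samples (RTT and IC)
are projected with the IC loadings and assigned the arc length of the
nearest grid point (ties take the smaller arc length). Dorsal and ventral
arms are fitted independently, each including the shared day-0 iPSC IC
samples. Genotype differences in pseudotime are tested per day with
Welch's two-sample t-test.

## Isoform usage

Isoforms pass the filter when the gene's total raw count exceeds 50 in
*every* sample ("all samples" is read as all 42; a per-region reading is
selectable) and the isoform's raw count exceeds 10 in every RTT or every IC
sample. Relative abundance weights counts by effective length:
`u_i = (c_i / l_i) / Σ_j (c_j / l_j)` — the share of the gene's transcript
molecules on that isoform. Per isoform and contrast the usages are compared
with an **exact** two-sided Mann–Whitney test (full enumeration of
assignments up to group size 8; the normal approximation only beyond): at
n = 3 vs 3 the 20 equally likely arrangements make 0.1 the smallest
attainable two-sided P, which is why the threshold is P ≤ 0.1 rather than
0.05. A gene is DIU when any isoform passes in at least 4 of 7 contrasts.

## Allele-specific expression

The ASE score of a SNP in a sample is `max(ref, alt) / (ref + alt)` — 0.5
is balanced bi-allelic, 1 purely mono-allelic; zero-coverage SNPs are
undefined. A gene is *bi-allelic* in a genotype when some SNP has score
< 0.85 with both allele counts > 5 in every sample of at least 4 strata
(with `min_contrasts = 1` this reduces to the whole-group validation
variant). Genes bi-allelic in at least one genotype are tested for
differential ASE: per stratum, the per-sample gene-level score — the
maximum over the gene's covered SNPs, matching the "any qualifying SNP"
aggregation of the flag — is compared between genotypes with the exact
Mann–Whitney test, flagging at P ≤ 0.1 in ≥4 strata. SNP-to-gene
aggregation by "any qualifying SNP" is a documented choice; "all SNPs" is
selectable.

## Cross-omics integration

Proteins are matched to genes one-to-one; proteins mapping to several genes
are dropped (duplicating them would pseudo-replicate the correlation
summaries). Pair correlation is Spearman over shared samples
(pairwise-complete), and the median and negative fraction are recomputed
from the pair table on demand.

Post-transcriptional events fit, per pair, ordinary least squares
`protein ~ intercept + β_gene·gene + β_group·group` with group coded IC = 0,
RTT = 1; the event flag requires β_gene significantly greater than 0
(one-sided) *and* β_group significantly different from 0 (two-sided), both
at BH-FDR < 0.05 within their coefficient families — genes whose protein
tracks their transcript but with a genotype-shifted intercept.

Regulator inference follows the GENIE3 scheme with term eigengenes as
targets (computed on RTT and IC jointly) and candidates restricted by
annotation to TF proteins and regulatory lncRNAs: per target, a
random-forest regression (√K candidates per split, impurity importance,
1000 trees, fixed seed, single-threaded for determinism), importances
normalized to sum to 1 per target, then the top 5 % of the TF-protein
interaction pool and the top 5 ‰ of the lncRNA pool become edges (global
pools per class, `floor`, at least one edge).

## Imprinting statistics

The association between imprinting and differential expression is the
two-sided Fisher exact test on the 2×2 table over the QC-passing universe,
reporting the conditional-MLE odds ratio with its exact interval. For the
primary data differential status uses FDR; validation-style analyses use
nominal P — both are parameters. Cross-study pooling is inverse-variance
random-effects meta-analysis: the between-study variance by iterative REML
(fixed-point updates, tolerance 1e-8, at most 100 iterations) and the
Hartung–Knapp adjustment (weighted residual variance; t-quantile on k−1
degrees of freedom). Zero cells take a Haldane 0.5 correction before
pooling. Promoter enrichment averages tag counts over TSS ± 3000 bp per
gene, compares imprinted against non-imprinted genes with Welch's t-test,
and draws an envelope of `n_random_sets` (default 100) random gene sets of
the imprinted-set size; the random pool includes all profiled genes,
matching a plain random draw.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure every stage assumes,
with all stochastic output a pure function of the config (which carries a
mandatory seed):

- **RNA**: 2,000 genes × 42 samples (2 genotypes × 7 strata × 3
  replicates); negative-binomial counts with a log-linear mean — baseline
  ~ N(4, 1.5) in log2 relative units, a latent developmental axis
  (position day/25, loading ~ N(0, 1) on 30 % of genes), a ventral-region
  offset on 20 % of genes, and planted RTT effects: 10 % of genes at
  |log2FC| = 2 in all strata, 25 transient genes at day 13 only, and a
  developmental delay of 15 days applied to RTT samples' axis position.
  Dispersions are inverse-gamma (mean ≈ 0.05); library sizes uniform on
  [1e6, 3e6]; 5 % of genes sit on chromosome X to exercise the exclusion
  step.
- **Proteome**: 300 proteins mapped to autosomal coding genes. Intensities
  track composition-corrected (median-of-ratios) log2 expression plus
  protein noise calibrated so each pair's correlation targets 0.5 — the
  correlation is defined in the normalized space every between-sample
  normalization works in, because a strong developmental axis shifts raw
  CPM by a day-correlated composition offset. Twenty pairs carry a ±2
  log2-unit RTT offset (post-transcriptional truth); 5 % of cells are
  deleted at random (MAR); intensities below each sample's 5th percentile
  are censored, and 30 proteins are pushed below that limit in one whole
  group (MNAR truth).
- **Isoforms**: 400 well-expressed genes split multinomially over 1–4
  isoforms (Dirichlet usages; effective lengths uniform on [500, 3000] bp),
  so isoform counts sum exactly to gene counts; 40 genes carry a
  genotype usage switch of 0.4 between two isoforms.
- **Allelic counts**: 500 SNPs (two per imprinted gene, the rest random);
  Poisson depths (mean 80; zero-depth rows never emitted); beta-binomial
  allele draws with intra-class correlation 0.005. Imprinted genes draw a
  major-allele fraction above 0.97; eight of them switch to 0.65 in RTT
  (gain-of-bi-allelic truth); all other genes are balanced.
- **TSS profiles**: Poisson tags in 100-bp bins over ±3000 bp, background
  1 per bin plus a Gaussian bump (height 3, scale 800 bp) at the TSS;
  imprinted promoters get a ×2 rate factor.
- **Gene sets**: 8 planted enriched sets built from same-sign differential
  genes, 32 random sets, and a developmental set of the 40 strongest axis
  genes used by the trajectory stage.

Default sizes keep full-bundle generation under a second and the complete
recovery suite within minutes on one CPU; they are the package's chosen
desk-scale study conditions, not fitted values. Where the emulated study
reports no effect-size distributions, the defaults above were chosen once
as realistic for bulk organoid RNA-seq and are documented rather than
asserted as the study's values.

What the generator does **not** emulate: batch effects, read-level
artifacts (mapping bias, GC content), peptide-level proteomics structure,
reference bias in allelic counts, phasing, and ontology-structured gene
sets. Passing recovery tests therefore demonstrate correctness of the
statistical machinery under the assumed models, not robustness to the
technical artifacts of real data.

## Numerical conventions

- BH FDR uses the standard step-up on sorted P with stable feature-id
  tie-breaks; FDR is never below its nominal P.
- GSEA rank ties break by feature id; permutation P values are floored at
  1/(n_perm + 1).
- Z-scoring of marker panels uses population-variance scaling (a scaled row
  has mean 0 and mean square 1); constant rows become zeros with a warning.
- Degenerate inputs: singleton eigengene sets return the standardized
  profile with membership 1 (warning); zero-coverage SNPs and all-zero
  gene-sample isoform cells are NA; a gene set spanning the whole ranked
  list has ES 0; equidistant spline projections take the smaller arc
  length.
- PCA component signs are arbitrary: trajectory models built from permuted
  sample orders can differ in polyline sign while assigning identical
  pseudotime, and eigengene orientation is pinned by the mean-profile
  convention.

## Known limitations

- The moderated linear engine treats log2-CPM as approximately normal;
  at very low counts a count model would behave differently.
- The variance stabilizer is a robust stand-in, not maximum-likelihood
  VSN; its contract (calibration + glog) is tested, its estimates are not
  interchangeable with VSN's.
- Jaccard clustering sees only gene overlap, not ontology structure, so
  parent/child terms with disjoint annotated genes are not merged.
- Exact Mann–Whitney enumeration is limited to group sizes ≤ 8 (beyond
  that the normal approximation is used); at the study's n = 3 this is
  exact.
- The permutation-count null nests a full GSEA per outer permutation; its
  cost scales as outer × inner permutations, and the defaults trade Monte
  Carlo error for runtime.
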