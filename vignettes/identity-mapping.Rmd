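---
title: "Discovering transcriptional identities and mapping them onto single cells"
author: "idmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering transcriptional identities and mapping them onto single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idmapr)
```

# The model

Tumor cell populations are heterogeneous: a bulk expression profile is a
mixture of a small number of latent transcriptional programs
("identities"), and different cell lines or tumors weight those programs
differently. `idmapr` implements a pipeline built on that premise:

1. **Salient gene selection.** A gene is informative about population
   structure when its 2-D scatter against a fixed anchor oncogene
   (MYC by default) splits the samples into well-separated density
   clusters. For every candidate gene we run DBSCAN on the raw
   (unstandardized) points `(gene, anchor)` in log2(TPM+1) space, over the
   radius grid `eps = 0.10, 0.11, ..., 1.21` (112 values). A gene is kept
   when some radius yields a pair of non-noise clusters that are large
   enough and far enough apart.
2. **Identity discovery.** The salient-gene submatrix `X` (genes x
   samples, non-negative) is factored as `X ~ W H` by NMF under the
   Frobenius objective, for every rank in a grid. The rank is chosen by
   the elbow rule on reconstruction error; Ward hierarchical clustering of
   the (L1-normalized) columns of `H` groups samples into identities, and
   each gene is assigned to the factor that dominates its row of `W`.
3. **Reverse NMF.** With `W` frozen, each single cell `x` is projected by
   non-negative least squares, `min ||x - W h||, h >= 0`; the cell's
   identity is the factor with the largest weight, and per-factor z-scores
   of `h` across all cells give comparable identity scores.
4. **Shift analysis.** Counting assigned cells per identity before and
   after a perturbation gives an identities-by-conditions contingency
   table. The chi-squared test of independence (no continuity correction)
   provides Pearson residuals `(O - E)/sqrt(E)`; the treated-column
   residual is the *residual score* of an identity — positive means the
   identity expanded under treatment. The same machinery applied within
   the expanded identity across cell clusters localizes which clusters
   drive the expansion.
5. **Phenotype association.** Identities are validated against orthogonal
   data: group-vs-rest Wilcoxon rank-sum tests on expression, CRISPR
   gene-effect and drug-AUC values; Pearson correlation of drug AUC with
   per-factor `H` z-scores; overlap fractions with hallmark gene sets;
   attribution of differentially expressed genes to identity gene groups;
   and chi-squared enrichment of drug classes among differentially
   responding drugs.
6. **TF linkage.** For multiome data, per-cell motif accessibility of a
   transcription factor is regressed (OLS) against the per-cell module
   score of its target gene set, within each condition. `R^2` quantifies
   the coupling and `delta R^2 = R^2(treated) - R^2(control)` nominates
   regulators whose target coupling is activated by a treatment.

# Parameters that matter

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `eps_grid` | 0.10–1.21 step 0.01 | log2(TPM+1) distance | density radius sweep for the gene/anchor scatter |
| `min_samples` | 3 | samples | DBSCAN core threshold; matches the smallest cluster size of interest |
| `min_max_expr`, `min_range` | 3, 3 | log2(TPM+1) | cell-line prefilters; "lower than" is strict so boundary values survive |
| `min_cluster_size` | 3 (strict `>`) | samples | cell-line mode demands more than 3 samples per cluster |
| `min_centroid_dist` | 3 (cell line), 4 (tumor) | log2(TPM+1) | absolute separation between cluster centroids |
| `min_separation` | 1 | log2(TPM+1) | single-linkage gap between the accepting pair (cell-line mode) |
| `round1_min_size`, `round2_min_size` | 10, 8 (non-strict `>=`) | basal samples | tumor two-round cluster-size floors |
| `k_grid` | 4–9 (configurable) | ranks | NMF rank candidates; the elbow rule picks an interior point |
| `n_restarts` | 10 | — | best-of random initializations, seeded `seed + i` |
| `mixture_margin` | 0.10 | relative | clusters whose top two factor means are this close are labeled mixtures |
| `n_bins`, `n_ctrl` | 24, 100 | genes | module-score control binning and per-gene control sample |

The distance thresholds are absolute, so the 2-D points are deliberately
*not* standardized: the same gene-expression unit (log2(TPM+1) for bulk,
log1p CP10k for cells) must be used throughout.

# Design choices in detail

**Boundary semantics.** The selection filters mix strict and non-strict
comparisons on purpose: cluster sizes must *exceed* 3 in cell-line mode
("more than 3"), while the tumor rounds require *at least* 10 and 8 basal
samples. Prefilters remove genes whose maximum or range is *lower than*
3, so a gene with range exactly 3 survives.

**Cluster separation.** We define the separation of a cluster pair as the
minimum point-to-point Euclidean distance between them (the
single-linkage gap). Other definitions (e.g. boundary-to-centroid) exist;
the metric is isolated in one place and only the cell-line mode uses it.

**DBSCAN determinism.** Border points (non-core points within `eps` of a
core point) are attached to the cluster of their *nearest* core neighbor
rather than first-come order, so results do not depend on sample order.
Noise points are excluded from every pair evaluation.

**NMF.** The objective is the Frobenius norm, optimized by Lee–Seung
multiplicative updates; each restart is seeded deterministically and the
best of `n_restarts` is kept. `W` columns are scaled to unit L2 norm with
the scale absorbed into `H`, after which factors are ordered by
descending total `H` mass and named `F0, F1, ...`. All labeling is
invariant to the internal factor permutation.

**The elbow rule** is formalized as the maximum discrete curvature: with
drops `d_k = err(k-1) - err(k)`, `k* = argmax (d_k - d_{k+1})` over
interior grid points, ties to the smallest k. A consequence worth knowing:
the boundary ranks of the grid can never be selected, so the grid should
extend at least one rank below the smallest plausible answer. The
synthetic-recovery analyses in this package therefore search `k = 2..8`
around the planted rank of 4.

**Mixture labels.** A sample cluster whose top two mean factor weights
differ by less than 10% (relative) is labeled `mixture:Fi+Fj` instead of a
single identity; the margin is exposed because no principled universal
value exists.

**Reverse-NMF input.** NNLS requires non-negative inputs, so cells are
normalized as `log1p(counts / total * 1e4)`. Identity scores are z-scored
over *all* cells pooled (not per condition), so pre- and post-treatment
scores live on one scale. Population (ddof = 0) standard deviations are
used for all z-scores in the package.

**Residual variant.** Residual scores are Pearson residuals
`(O - E)/sqrt(E)`, the residual field of the standard chi-squared test;
standardized residuals (divided by `sqrt((1-r_i)(1-c_j))`) would sharpen
per-cell calibration but change the reported magnitudes, and the Pearson
form is kept as the default output.

**Module scores.** The per-cell gene-set score is the set mean minus the
mean of an expression-matched control pool: genes are binned by average
expression (24 bins) and up to 100 control genes are drawn, seeded,
from each set gene's bin, *excluding the set genes themselves*. With the
control pool held fixed the score is exactly linear in the set's
expression; under the default re-binned sampling the linearity is
approximate, because a strong set-wide shift moves the set genes across
bins. A `control_genes` override supports the self-control configuration
(score identically zero), used by the tests.

**Multiplicity.** "Adjusted p-values" are Benjamini–Hochberg throughout;
the drug-level flag feeding the class-enrichment test uses BH-adjusted
p < 0.05.

# What the synthetic generators emulate

`simulate_bulk()` plants `k_true = 4` programs in 400 genes x 40 samples:
each program owns a disjoint block of marker genes with log-scale
on-levels from U(4, 8) over a U(0, 0.3) baseline (so markers clear the
absolute selection thresholds the way strong markers do in real
log2(TPM+1) data), 10% of each block is shared with the next program,
samples carry one planted identity with weight ~U(0.9, 1.1), Gaussian
noise (sd 0.3) is added, and the anchor gene is an extra marker of the
heaviest program, making it bimodal across samples. The other half of the
genes are flat noise, giving the selection stage true negatives.

`simulate_single_cells()` draws each cell's identity from its condition's
composition (uniform in the control arm; +0.15 mass on F0 in the treated
arm), perturbs the identity's normalized `W` column with a Dirichlet draw
(per-gene concentration 50), scales to 2,000 expected counts and
Poisson-samples. Counts are Poisson rather than negative binomial: for
testing NNLS projection and composition shifts the extra dispersion
parameter adds nothing, and the Poisson limit keeps the noiseless checks
exact.

`simulate_drug_auc()` couples one designated drug linearly to the
z-scored planted weight of F0 (slope −1, noise sd 0.5, so the planted
PCC is −0.894); all other drugs are pure noise.

`simulate_tf_multiome()` gives one planted TF and 20 decoys per-cell
motif accessibility `a ~ N(condition mean, 1)` and plants
`target score = slope * a + e` with slope 1 and `e ~ N(0, 1)` under
treatment only, so the closed-form
`R^2 = slope^2 var(a) / (slope^2 var(a) + noise^2) = 0.5` holds in the
treated arm and 0 in the control arm. The noise `e` is shared across a
TF's target genes within each cell (pathway-level noise, plus sd 0.05
per-gene jitter): with independent per-gene noise the mean over targets
would average the noise away and inflate the realized `R^2` above the
planted value.

What the generators do **not** emulate: batch effects, doublets, ambient
RNA, cell-cycle structure, negative-binomial overdispersion, gene-gene
correlation beyond the planted programs, and realistic marker sparsity.
Passing the recovery suite therefore demonstrates the correctness of the
algorithms under the stated model, not robustness to every artifact of
real single-cell data.

# Numerical choices and degenerate inputs

- NMF convergence: relative error change below 1e-7 over a 10-iteration
  window, at most 1000 iterations; denominators are guarded with 1e-12.
- NNLS: Lawson–Hanson active set; solutions satisfy the KKT conditions to
  1e-8 (verified against exhaustive support enumeration in the tests).
- Ties: argmax assignments (gene groups, cell identities) break to the
  lowest factor index; the elbow ties to the smallest interior rank.
- Degenerate inputs are flagged, not crashed on: all-zero H columns
  become `unassigned` samples, all-zero gene rows `unassigned` genes,
  constant accessibility yields `NA` R², zero-variance correlation inputs
  return a flagged row, and empty contingency margins raise an error
  naming the margin.
- Every stochastic step (generators, NMF restarts, module-score control
  sampling) flows from one integer seed through named sub-seeds, so a
  full pipeline rerun is bit-identical.

# Problem sizes used by the recovery analyses

The bundled recovery analyses (tests and `scripts/acceptance.R`) sweep 20
seeds at the generator defaults: 400 x 40 bulk matrices, 500 cells per
condition for mapping and shift recovery, 30-drug AUC tables, and
5,000 cells per condition with 20 decoy TFs for the linkage analysis —
sizes at which each property is sharply testable while a full sweep
completes in minutes on one CPU.

# Known limitations

- The two-round tumor mode consumes a caller-supplied basal-sample
  partition; PAM50 subtyping itself is out of scope.
- Motif accessibility scores and TF target lists are consumed
  precomputed; peak calling and motif matching are out of scope.
- No consensus-NMF stability analysis or Bayesian rank selection; the
  elbow rule is the single rank criterion.
- No per-cell uncertainty on the NNLS weights.
- Identity labels are structural (F0, F1, ...); biological annotation of
  what each identity represents is left to the analyst.
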