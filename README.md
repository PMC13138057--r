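# idmapr

Bulk tumor expression profiles mix a small number of latent
transcriptional programs — "identities" — and treatments reshape how a
cell population distributes over them. `idmapr` is an R package for
analysts who want to discover those identities from bulk RNA-seq,
project them onto single cells, and quantify how perturbations shift the
population. It implements:

- **Salient gene selection**: DBSCAN clustering of each gene's 2-D
  expression scatter against an anchor oncogene (MYC), sweeping
  `eps = 0.10 ... 1.21` and keeping genes whose scatter splits samples
  into large, well-separated clusters (one-round cell-line mode and
  two-round tumor mode).
- **Identity discovery**: non-negative matrix factorization
  `X ≈ W H` on the salient-gene matrix (Frobenius objective,
  multiplicative updates, best of seeded restarts), rank chosen by the
  elbow rule on reconstruction error, sample identities by Ward
  clustering of `H`, gene groups by the dominant factor of `W`.
- **Reverse NMF**: per-cell non-negative least squares
  `min ‖x − W h‖, h ≥ 0` against the bulk-derived `W`, assigning each
  cell its dominant identity plus pooled z-scored identity scores.
- **Shift analysis**: identity × condition contingency tables,
  chi-squared tests, and Pearson residual scores `(O − E)/√E` whose
  treated-column values quantify identity expansion (+) or shrinkage
  (−), with per-cluster decomposition of an expansion.
- **Phenotype association**: group-vs-rest Wilcoxon tests (expression,
  CRISPR dependency, drug AUC), Pearson correlation of drug AUC with `H`
  z-scores, hallmark gene-set overlaps, DEG-to-identity attribution and
  drug-class enrichment, with Benjamini–Hochberg adjustment.
- **TF linkage**: per-cell gene-set module scores (bin-matched
  controls), per-condition OLS `R²` between motif accessibility and
  target-set score, and `ΔR² = R²(treated) − R²(control)` to nominate
  treatment-activated regulators.
- **Seeded synthetic generators** for every input type, with planted
  ground truth, so each stage has a parameter-recovery test surface.

Results come back as tibbles (with `tidy()`, `glance()` and
`autoplot()` methods), so the package composes with the tidyverse.

## Worked example

Simulate a bulk cohort with four planted programs, discover the
identities, map single cells, and score a treatment-induced shift:

```r
library(idmapr)

b   <- simulate_bulk(seed = 42)                      # 401 genes x 40 samples
sal <- select_salient_genes(b$expr, gene_selection_config("cell_line"))
nrow(sal)
#> [1] 201
head(sal, 3)
#> # A tibble: 3 × 6
#>   gene  best_eps centroid_dist size_small size_large separation
#>   <chr>    <dbl>         <dbl>      <int>      <int>      <dbl>
#> 1 MYC      NA             NA           NA         NA       NA
#> 2 G0182     0.35          10.5          4          7       10.2
#> 3 G0174     0.28          10.5          4          5       10.1

m <- fit_identity_model(b$expr, genes = sal, k_grid = 2:8, seed = 42)
m
#> <identity_model> k = 4, 201 genes x 40 samples
#> identity sizes:
#> F0 F1 F2 F3
#> 10 10 10 10
```

The selection kept the 200 planted marker genes (plus the anchor) and
rejected the 200 flat noise genes; the elbow recovered the planted rank
4 and every sample landed in its planted program. Now project single
cells (500 per condition; the treated arm plants +0.15 composition mass
on F0) and test the shift:

```r
sc    <- simulate_single_cells(b$truth, seed = 43)
cells <- map_cells(normalize_cells(sc$counts), m, cell_meta = sc$cell_meta)
shift <- identity_shift(cells, "control", "treated")
shift
#> <shift_result> chi2 = 19.94, dof = 3, p = 0.000175
#> most expanded identity: F0 (residual 2.506)
tidy(shift)
#> # A tibble: 4 × 5
#>   identity n_control n_treated residual_score expanded
#>   <chr>        <int>     <int>          <dbl> <lgl>
#> 1 F0             122       184          2.51  TRUE
#> 2 F1             124       102         -1.03  FALSE
#> 3 F2             137       102         -1.60  FALSE
#> 4 F3             117       112         -0.234 FALSE
```

The planted expansion is recovered: F0 gains cells under treatment
(positive residual score), the other identities shrink. `autoplot(m)`
draws the elbow curve, `autoplot(shift)` the residual-score bars, and
`autoplot(cells)` the per-condition composition. `run_pipeline()` chains
all stages from a single YAML/list config with per-stage provenance
files; see the vignette in `vignettes/identity-mapping.Rmd` for the
model, parameter and design details.

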