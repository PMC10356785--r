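# graftscape

Downstream analysis of immune infiltrates in kidney transplant biopsies
profiled by iterative multiplexed immunofluorescence (MILAN-style panels:
per-cell coordinates, nuclear size, and one mean fluorescence intensity per
marker), plus single-cell-derived deconvolution of bulk transcriptomics. The
package is aimed at computational pathology and transplant-immunology groups
who have per-cell tables and compartment annotations in hand and want the
statistics between those tables and the figures to be reproducible and
testable.

Four analysis stages, each exercisable on synthetic data the package
generates itself:

1. **Consensus phenotyping** — per-region Z-score normalization of MFIs
   (trimmed to [0, 5]); stratified proportional subsampling
   (S<sub>i</sub> = S·N<sub>i</sub>/M with largest-remainder rounding);
   three clustering backends (Leiden on a Jaccard-weighted 30-NN graph, a
   self-organizing map with Ward metaclustering, k-means) whose annotated
   labels are combined by a two-of-three majority vote ("NOS" on full
   disagreement); label extrapolation to all cells via a UMAP template
   (≤500 cells/type) and a 100-nearest-neighbor vote; myeloid re-clustering
   on a 13-marker monocyte panel.
2. **Spatial statistics** — in-silico microdissection into glomerular,
   large-vessel, small-vessel, tubular and interstitial compartments;
   compartment composition and glomerular in/out shares (Mann–Whitney
   across samples); distance-to-closest-glomerulus enrichment curves; and a
   permutation-null neighborhood enrichment test: the number of ordered
   (source, target) cell pairs within distance d (d = 10…100 µm) is compared
   with N = 1000 relabelings that keep every cell's position and the
   sample's cytometry fixed, freeze structural cells, and yield the add-one
   empirical p-value p = (1 + #{perm ≥ obs})/(N + 1) plus a signed
   exceedance statistic.
3. **Deconvolution** — droplet QC gates (<400 / >10,000 detected genes or
   >25% mitochondrial excluded); probeset collapse by highest average
   expression; a KTB18-style signature matrix (per-type mean linear
   expression, minimum-expression 0.1, 300–500 barcode genes per type
   selected by rank-sum/BH-gated fold change, the barcode size chosen by
   minimizing the matrix condition number); non-negative least-squares
   estimation of cell-type fractions min<sub>f≥0</sub> ‖Sf − b‖₂ with
   simplex renormalization; pseudobulk validation with per-type Pearson r.
4. **Association reporting** — Spearman/Pearson correlation of cell-type
   frequencies with an inflammation-severity scalar (Fisher-z 95% CI, exact
   permutation p for small n) and Kruskal–Wallis + Dunn group comparisons.

See `vignettes/graftscape-methods.Rmd` for the models, parameter defaults,
numerical choices and limitations.

## Worked example

Simulate a 2,000-cell biopsy field in which 60% of NK cells are attracted to
macrophages (σ = 15 µm), phenotype the cells from raw marker intensities,
and test the NK→macrophage neighborhood enrichment:

```r
library(graftscape)

spec <- tissue_spec(
  n_cells = 2000, seed = 11,
  colocalization = list(list(attractor = "Macrophage", attracted = "NK",
                             sigma = 15, fraction = 0.6)))
tissue <- simulate_tissue(spec)

model <- block_marker_model(names(spec$abundance),
                            markers = sprintf("M%02d", 1:10), separation = 5,
                            region_gain = c(S1_R1 = 1, S1_R2 = 1.2),
                            region_shift = c(S1_R1 = 0, S1_R2 = 1.5))
cells <- simulate_markers(tissue$cells, model, seed = 12)
cells <- normalize_mfi(cells, colnames(model$log_mean))
res <- phenotype_cells(cells, colnames(model$log_mean),
                       signatures_from_model(model), seed = 13)
mean(res$cells$phenotype == res$cells$phenotype_true)
#> [1] 0.9925

phenotyped <- assign_compartments(res$cells, tissue$map)
nt <- neighborhood_test(phenotyped, "NK", "Macrophage",
                        d = c(20, 30, 40), n_perm = 1000, seed = 14)
nt[, c("d", "observed", "perm_mean", "p_enrich", "signed_exceedance")]
#> # A tibble: 3 × 5
#>       d observed perm_mean p_enrich signed_exceedance
#>   <dbl>    <int>     <dbl>    <dbl>             <dbl>
#> 1    20      248      176. 0.000999              1000
#> 2    30      490      373. 0.000999              1000
#> 3    40      774      635. 0.000999              1000
```

The consensus phenotypes recover 99.3% of the simulated ground truth; at
every tested radius the observed NK→macrophage pair count exceeds all 1,000
permutation counts, so the enrichment p-value is at its floor of
1/1001 ≈ 0.001 and the signed exceedance sits at +1000 (all permutations
below the observation) — the planted attraction is detected.

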