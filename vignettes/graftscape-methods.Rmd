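---
title: "Methods: spatial phenotyping and deconvolution of allograft infiltrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial phenotyping and deconvolution of allograft infiltrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftscape)
```

`graftscape` implements the downstream computational analysis of immune
infiltrates in kidney transplant biopsies profiled by iterative multiplexed
immunofluorescence (one mean fluorescence intensity, MFI, per marker per
segmented cell), together with single-cell-derived deconvolution of bulk
expression. The pipeline starts at the per-cell table — segmentation, image
registration and compartment annotation are upstream concerns — and covers
four stages: consensus phenotyping, in-silico microdissection with spatial
statistics, signature-matrix deconvolution, and association reporting. A
first-class synthetic-data module generates tissues, marker intensities,
single-cell counts and bulk mixtures with known ground truth, so that every
stage is testable end to end without access to patient data.

## Consensus phenotyping

**Normalization.** MFI values are standardized to Z-scores within each
imaging region (`normalize_mfi()`), marker by marker, which removes
region-level staining batch effects (multiplicative gain and additive
offset). Z-scores are trimmed to $[0, 5]$ so outliers cannot dominate the
clustering. Two degenerate cases the rule itself does not cover are resolved
as follows: a region×marker combination with zero variance, and a region
holding a single cell, both yield $Z = 0$ — the cells stay usable and the
marker is simply uninformative there. Note that trimming at 0 discards the
below-mean half of the distribution; this is intentional (markers are
informative through positivity) and the automated annotation signatures are
built to match (negative standardized values floored at zero).

**Subsampling.** Clustering operates on a stratified proportional random
subsample (default 50,000 cells): sample $i$ with $N_i$ cells out of
$M = \sum_{i=1}^{P} N_i$ contributes $S_i = S \cdot N_i / M$ cells. Real
quotas are rounded by the largest-remainder (Hamilton) method with ties
broken in sample order, so $\sum S_i = S$ exactly and every rounded quota is
within 1 of its real value. The rounding rule is our choice; the quota
formula fixes only the real-valued targets.

**Three backends, one vote.** The subsample is clustered three ways
(`run_backends()`): (1) community detection on a Jaccard-weighted $k$-nearest-
neighbor graph ($k_{\mathrm{graph}} = 30$), using Leiden with the modularity
objective — graph construction and objective follow the PhenoGraph recipe,
and Leiden was chosen over Louvain for its refinement guarantees and
deterministic seeded behavior; (2) a self-organizing map (batch algorithm,
hexagonal grid capped at 10×10 and shrunk for small inputs) whose code
vectors are metaclustered by Ward hierarchical clustering; (3) $k$-means.
The number of communities found by the graph backend fixes $k$ for the other
two. Each backend's clusters are mapped to phenotypes by correlating the
cluster's mean Z-profile with expected phenotype signatures
(`annotate_clusters()`; assignments below a minimum Pearson correlation,
default 0.3, become "NOS"). Automating this step replaces per-cluster expert
annotation, which cannot be reproduced in software; the signature tables make
the expert knowledge explicit and auditable. The vote (`consensus_vote()`)
then happens at the phenotype level, not the cluster-id level — cluster ids
are arbitrary and incomparable across backends, so a meaningful majority can
only be taken after annotation. A cell keeps a phenotype if at least two
backends agree; full disagreement yields "NOS".

Community detection routinely over-partitions a single homogeneous
population; this is harmless here because split clusters are annotated back
to the same phenotype before the vote.

**Extrapolation.** Labels are extended to the full dataset
(`extrapolate_labels()`) from a template of at most 500 cells per annotated
type: a 2-D UMAP is fitted to the template, all cells are projected into it,
and each receives the modal label of its 100 nearest template cells. Ties
are broken by the smaller mean distance to the tied voters, then by label
order. "NOS" cells are excluded from the template — a vote category, not a
cell population, extrapolating it would spread disagreement artifacts. A PCA
embedding is available (`method = "pca"`) where strict cross-platform
determinism matters more than embedding quality.

**Myeloid refinement.** `subcluster_myeloid()` re-runs the whole chain on
the dendritic-cell/macrophage/neutrophil subset restricted to a 13-marker
monocyte panel, writing refined labels to a separate column so parent labels
are preserved.

## In-silico microdissection and spatial statistics

Compartment maps hold labeled simple polygons (glomeruli, large vessels,
small vessels, tubular mask) in image coordinates (µm, origin top-left, y
downward); the interstitium is the complement. `assign_compartments()` is
boundary-inclusive point-in-polygon with the fixed precedence glomerular >
large vessel > small vessel > tubular, our resolution of overlapping
annotations. Distances are Euclidean in the section plane; no 3-D
correction is attempted.

`distance_to_glomerulus()` returns the distance to the nearest glomerular
boundary (0 inside), computed against all polygon edges via a segment
nearest-neighbor query; `enrichment_curve()` accumulates, over a distance
grid, the percentage of the total cell population belonging to a type within
distance $x$ of its closest glomerulus — curves are monotone and saturate at
the type's overall share.

**Neighborhood permutation test.** For cell types $s, t$ and radius $d$,
the statistic is the number of ordered $(s, t)$ pairs of distinct cells at
distance $\le d$ (`neighborhood_counts()`; a kd-tree radius search that is
contractually equal to the brute-force double loop, which the test suite
enforces). The null (`neighborhood_test()`) randomizes cell identities while
preserving the tissue's cytometry and every cell's coordinates: labels of
non-structural cells are permuted uniformly within each sample; structural
cells (tubular and endothelial, configurable) are frozen to avoid bias from
tissue architecture. Permutation is within-sample because pooling labels
across samples would break per-sample cytometry preservation. With $N$
permutations (default 1000, evaluated at $d = 10, \dots, 100$ µm in steps of
10), the enrichment p-value uses the add-one estimator
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(N + 1)$, which cannot
return zero at finite $N$; depletion is analogous. The signed exceedance
statistic reported per $(s, t, d)$ is the number of permutations *below* the
observed count when the observation exceeds the permutation median, and
minus the number *above* it otherwise; both one-sided exceedance counts are
retained in the result so either sign convention can be plotted. Ordered
(directional) counts are the default, with `ordered = FALSE` available —
the distinction only matters for asymmetric neighborhoods, and both readings
are exposed deliberately.

## Signature-matrix deconvolution

`qc_filter()` applies the droplet single-cell quality gates: cells with
fewer than 400 or more than 10,000 detected genes, or with *strictly more*
than 25% mitochondrial transcripts, are excluded; boundary cells are kept,
matching the strict inequalities of the stated rules. `collapse_probesets()`
reduces microarray probesets to genes by keeping the probeset with the
highest average expression (ties: lexicographically first probe id).

`build_signature()` constructs a genes × types signature matrix in linear
("anti-logged") expression space from labeled single cells: stratified
sampling of 10,000 cells by default; per-type mean expression; genes whose
maximum per-type mean falls below 0.1 dropped (the droplet-data threshold);
per type, candidate barcode genes are those significantly up-regulated
against all other types (two-sided Wilcoxon rank-sum, normal approximation
with tie correction, Benjamini–Hochberg $q < 0.05$, positive fold change),
ranked by log fold change. The rank-sum/BH gate is our concrete,
reproducible stand-in for the proprietary feature selection inside
CIBERSORT-class tools. For every barcode size $G \in [300, 500]$ the union
of per-type top-$G$ genes defines a candidate matrix; the $G$ minimizing the
2-norm condition number wins (smallest $G$ on ties), and the scan is
returned for inspection. Types with fewer than $G_{\min}$ candidates relax
the bound with a warning.

`estimate_fractions()` solves, per bulk sample over the shared genes,
$\min_{f \ge 0} \| S f - b \|_2$ by non-negative least squares and
renormalizes $f$ to the simplex, reporting the relative residual. NNLS is a
documented stand-in for ν-SVR: it preserves the non-negativity and
linear-mixing model while remaining free of tuning parameters.
`pseudobulk()` aggregates labeled cells into validation mixtures with known
fractions, and `evaluate_deconvolution()` reports per-type Pearson $r$
across samples plus the median over evaluable types; zero-variance types are
flagged rather than silently dropped, and `merge_types()` supports pooling
indistinguishable subsets (e.g. NK subsets) beforehand.

## Association reporting

`severity_correlation()` relates a cell type's frequency to a per-biopsy
inflammation-severity scalar in $[0,1]$ (taken as given input) by Spearman
or Pearson correlation. The 95% CI uses the Fisher z-transform —
$\mathrm{SE} = 1/\sqrt{n-3}$ for Pearson and the rank-based variant
$\sqrt{(1 + r^2/2)/(n-3)}$ for Spearman — our choice where no CI
construction is prescribed. The p-value is exact by full enumeration of the
permutation null for $n \le 8$ (40,320 permutations; the `exact_n` argument
moves the switch, but enumeration beyond $9!$ is refused as computationally
disproportionate) and the asymptotic $t$-approximation otherwise.
`group_compare()` runs the Kruskal–Wallis omnibus test with Dunn's
rank-based pairwise $z$ comparisons (tie-corrected) and Benjamini–Hochberg
adjustment by default, the correction chosen where none is stated; singleton
groups join the omnibus test and are flagged in the pairwise table.

## The synthetic-data module

`simulate_tissue()` emulates one field of view: glomeruli as non-overlapping
discs, large vessels as rectangles, small vessels as small discs, the
tubular mask as a Boolean union of discs grown until a Monte-Carlo coverage
target is met — the simplest geometry supporting point-in-polygon and
distance queries. Cells are placed by rejection sampling against
per-phenotype compartment odds (an odds multiplier of $o$ for a compartment
yields an inside/outside odds ratio of exactly $o$ against the area
fraction), then co-localization moves a stated fraction of an attracted
type to a random attractor cell plus an isotropic Gaussian displacement of
scale $\sigma$ — a single tunable effect size for power analyses.
`simulate_markers()` draws log-normal MFIs with per-region gain/shift batch
effects and additive noise, floored at zero. `simulate_sc_counts()` draws
negative-binomial counts with disjoint per-type marker blocks, log-normal
library sizes, and optional injected QC violators (low-complexity and
high-mitochondrial cells). `simulate_mixtures()` mixes signature columns
with Dirichlet fractions and optional log-normal ("5%" = sd 0.05 on the log
scale) or additive noise. All simulators are bit-reproducible for a fixed
seed; `derive_seeds()` splits one master seed into independent stage
streams.

What the generator does *not* emulate — segmentation errors, marker
spillover, autofluorescence gradients within a region, doublets, realistic
nephron anatomy, cross-platform batch structure between single-cell and bulk
data — bounds what passing tests show: they validate the statistical
machinery under its stated model, not robustness to the full messiness of
real images or arrays.

## Reference study conditions and verification

The package's property suite and `scripts/acceptance.R` exercise the
pipeline at desk-scale study conditions chosen once: null and power
calibration of the neighborhood test on 200 and 100 simulated tissues of
~1,500 cells (200 permutations, default five-phenotype cytometry; planted
attraction $\sigma = 15$ µm, 60% of NK cells attracted to macrophages);
exact-equivalence checks of the spatial primitives against brute-force
oracles on twenty 500-cell instances; consensus phenotyping on 20,000 cells
with ten phenotypes at 4-sd centroid separation (5,000-cell clustering
subsample); stratified-sampling exactness over 1,000 random configurations;
and an 18-type deconvolution with 450 marker genes per type among 9,500
genes, 150 cells per type — enough candidates that barcode lists stay inside
the configured $[300, 500]$ bounds. Under these conditions the suite
verifies, among others: empirical type-I error of the neighborhood test at
$\alpha = 0.05$ within $[0.02, 0.09]$ with uniform p-values
(Kolmogorov–Smirnov); power $\ge 90\%$ at $d \in \{20, 30, 40\}$ µm;
phenotyping accuracy $\ge 95\%$; noiseless mixture recovery to $10^{-6}$;
and median per-type Pearson $r \ge 0.9$ under 5% noise.

## Known limitations

* Cluster annotation quality is bounded by the supplied signatures; profiles
  correlated across phenotypes degrade the vote (by design, into "NOS"
  rather than into confident errors).
* The UMAP embedding used for extrapolation is deterministic per seed but
  not guaranteed bit-identical across BLAS builds; the PCA fallback is.
* NNLS fractions are renormalized to the simplex, so an unmodeled cell type
  in the bulk inflates the modeled fractions proportionally.
* The permutation test conditions on observed cell positions; it tests label
  exchangeability, not point-process models of cell placement.
* Empirical p-values are discrete at finite $N$; with $N = 200$ the smallest
  attainable p is $1/201$.
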