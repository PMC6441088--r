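# latmorph

Functional lateralisation of the human brain, analysed end to end: from
per-term activation volumes on a left-right symmetric grid to laterality
index (LI) maps, significantly lateralised regions, a low-dimensional
"morphospace" of lateralisation profiles with a Pareto triangularity test
and archetype maps, and the relationship between hemispheric dominance and
corpus-callosum connectivity.

The package is written for neuroimaging methodologists who want a tested,
reproducible reference implementation of this analysis chain, together
with a synthetic-data generator that plants known archetype and
dominance-connectivity structure so every stage can be validated against
ground truth.

## The analysis in brief

* **LI maps.** Each volume is split at the interhemispheric plane, each
  half smoothed (Gaussian, FWHM 6 mm, mask-renormalised), the left half
  flipped and subtracted from the right: `LI = smooth(R) - flip(smooth(L))`,
  positive = right-lateralised.
* **Lateralised regions.** PCA of the term-by-term covariance (components
  with eigenvalues above the grand average retained, varimax-rotated with
  Kaiser normalisation), voxelwise GLM of LI on the rotated loadings, and
  a rotation-aware maximal-statistic permutation test: permute the rows of
  the unrotated loading matrix, re-rotate, refit, and compare each real
  spatial-map value against the distribution of map-wide extrema
  (two-tailed FWE, clusters of at least 20 voxels).
* **Morphospace.** Maps are denoised by component reconstruction; their
  similarity is the voxelwise dot product with negatives zeroed; spectral
  embedding uses the eigendecomposition of the symmetric normalised graph
  Laplacian `L = I - D^(-1/2) W D^(-1/2)` (eigenvalues ascending, first
  dimension dropped). Triangularity of a 2-D subspace is the **t-ratio**:
  convex-hull area over minimal-enclosing-triangle area, compared against
  voxel-permutation null map sets with Bonferroni correction over
  subspaces. Archetype maps are the voxelwise regression of denoised LI on
  embedding coordinates, evaluated at the triangle vertices.
* **Connectivity.** Hemispheric dominance is
  `atan2(right, left) - pi/4` (0 = bilateral, ±pi/4 = unilateral) at each
  voxel's largest-|z| component. Lateralised and non-lateralised pools are
  contrasted in connection probability and replicability-weighted axonal
  water fraction by repeated 5% subsampling; the graded
  dominance-connectivity relationship is the Pearson correlation of bin
  means over geometrically spaced connection-probability bins (smallest
  width = 1/n_subjects), optionally partialling out mean bilateral
  activity.

## Worked example

```r
library(latmorph)

grid <- make_symmetric_grid(c(12, 12, 12), "ellipsoid")
grid
#> <lat_grid> 12x12x12 voxels (2 mm), mirror axis 1, 912 in-mask voxels (456 homologous pairs)

gen <- generate_term_maps(grid, n_terms = 60, n_archetypes = 3,
                          noise_sd = 0.1, seed = 11)
li <- li_matrix(gen$maps, fwhm_mm = 6)

model <- rotate_model(fit_pca(li))
model
#> <component_model> 60 terms, 5 retained components (97.3% variance)
#>   varimax-rotated (Kaiser normalisation)

sig <- permutation_significance(li, model, n_perm = 500, seed = 31, grid = grid)
sig$n_significant_components   # components with FWE-significant clusters
#> [1] 2
sum(sig$any)                   # significantly lateralised voxels
#> [1] 107

pl <- embed_pipeline(li, n_dims = 5)
t_ratio(pl$embedding$coords[, 1:2])
#> <t_ratio_result> hull area 1.87984e-05, min triangle area 1.99279e-05, t-ratio 0.943318
```

The five retained components (97.3% of LI variance) compress the 60
redundant term maps; two of them carry family-wise-significant
lateralised clusters, 107 voxels in all. The embedded maps fill 94% of their
minimal enclosing triangle — `t_ratio_null_test()` then tells you whether
that triangularity exceeds what voxel-permutation null maps produce, and
`archetype_maps()` reconstructs the LI pattern at each triangle vertex.

`run_pipeline(default_config(seed = 1))` chains every stage — synthesis,
LI maps, significance, embedding, triangularity test, archetypes,
connectivity generation and contrasts — and returns a flat report of all
statistics, deterministic in the seed.

The judge-agreement helper reproduces screening bookkeeping exactly:
`agreement_rate(3107, 422, 2309)$percent` is `88`.

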