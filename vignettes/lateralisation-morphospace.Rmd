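---
title: "Mapping functional lateralisation and its morphospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping functional lateralisation and its morphospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latmorph)
```

## The problem

Many cognitive functions engage the two cerebral hemispheres unequally.
Given a large collection of volumetric activation maps — one per cognitive
term, all registered to a left–right symmetric template — three questions
arise. Which voxels are *significantly* lateralised, once the redundancy
among thousands of overlapping terms is accounted for? Does the collection
of lateralisation profiles occupy a low-dimensional "morphospace" with a
small number of extremal archetypes, as Pareto-optimality theory predicts
for trait trade-offs? And is the degree of hemispheric dominance of a
region related to how strongly it connects to the opposite hemisphere
through the corpus callosum?

`latmorph` implements the full analysis chain for these questions, plus a
synthetic-data generator with planted ground truth, so that every stage —
laterality indices, component detection, embedding, triangularity testing,
archetype reconstruction, connectivity contrasts — can be verified end to
end on data whose answers are known.

## Laterality-index maps

A volume on a symmetric grid is split into hemisphere halves; each half is
smoothed with a Gaussian kernel (default FWHM 6 mm on a 2 mm grid, the
conventional scale for meta-analytic maps); the left half is flipped and
subtracted from the right half. Positive LI values mean stronger
right-hemisphere evidence. Halves are smoothed *separately* so no signal
leaks across the midline, and the kernel is renormalised inside the brain
mask so constants are preserved at mask edges (mass is conserved wherever
the truncated kernel support stays inside the mask). Smoothing before
flipping equals flipping before smoothing for a symmetric kernel, so the
ambiguity in the order of those two steps is immaterial.

The grid abstraction (`make_symmetric_grid`) mirrors hemispheres across the
first axis with an even extent — every voxel has exactly one homologue and
there is no shared midline voxel. Real data in a symmetric MNI space use a
world-coordinate x-flip; the half-grid indexing here is the analogue of
that step with the registration problem out of scope.

## Finding significantly lateralised regions

Term maps are highly redundant, so the terms-by-voxels LI matrix is first
reduced by principal component analysis of the term-by-term covariance
(terms are variables, voxels observations). Components with eigenvalues
above the grand average are retained and varimax-rotated with Kaiser
normalisation (SVD-based iteration, tolerance 1e-6 on the criterion, at
most 1000 iterations; the criterion trace is returned and is
non-decreasing). Voxelwise spatial maps are then obtained by regressing
each voxel's across-term LI vector on the rotated loadings.

Two numerical choices deserve comment.

**The intercept is orthogonalised against the loadings.** When term
profiles are near-convex mixtures of a few patterns, the constant vector
lies (almost) inside the loading span and the naive `[1, loadings]` design
is ill-conditioned: its OLS coefficients explode under permutation,
destroying the power of the significance test. Giving the loadings
priority — regress on the loadings, and let an intercept direction
orthogonal to them absorb any residual mean — leaves the betas equal to the
plain projection coefficients (for orthonormal loadings, `t(L) %*% y`),
keeps the fit well conditioned, and reduces to the ordinary
intercept-model when the loadings are far from the constant vector.

**The maximal statistic is the beta value.** Significance uses the
rotation-aware maximal-statistic permutation test: permute the rows of the
*unrotated* loading matrix, re-apply varimax, refit the GLM, and record the
single largest and smallest map value; a voxel is significant (two-tailed,
family-wise corrected) when its real value strictly exceeds the
`1 - alpha/2` fraction of null maxima (or falls below the corresponding
minima), and survives in a cluster of at least 20 voxels under
26-neighbourhood connectivity. The beta maximum is exchangeable under this
permutation scheme and calibrates on null data. The z maximum (beta/SE) is
available behind a flag but is *anti-conservative* here: components fitted
to a dataset always leave smaller residuals than row-permuted ones, so real
z values are systematically inflated relative to the permutation null —
on simulated exchangeable-hemisphere data the z variant flagged every null
dataset while the beta variant stayed within the nominal error rate.

The 26-neighbourhood for clusters is the most permissive standard choice;
cluster filtering is applied per component and per sign.

## Morphospace embedding and the triangularity test

LI maps are "denoised" by reconstructing them from the retained components
(fitted values of the voxelwise GLM, mean term re-added), their pairwise
similarity is the voxelwise dot product with negative entries zeroed and
the diagonal set to zero, and the maps are embedded by eigendecomposition
of the symmetric normalised graph Laplacian. Eigenvalues are sorted
ascending; the first, zero-eigenvalue dimension is non-informative and
dropped; coordinates are degree-rescaled eigenvectors with a fixed sign
convention (largest-magnitude entry positive). Raw eigenvectors are a
flag: note that the choice *does* matter for the triangularity statistic —
per-point degree rescaling is not an affine map — but the degree-rescaled
variant is the default.

Triangularity of a 2-D subspace is quantified by the t-ratio: convex-hull
area divided by the area of the minimal enclosing triangle, 1 for a
perfectly triangular cloud, and invariant under affine maps of the
coordinates. The minimal triangle is found by fixing each hull edge in
turn as the flush side (at least one side of the optimum is flush with a
hull edge) and minimising the area over the two remaining support-line
angles — a coarse angle grid plus Nelder-Mead polishing; the test suite
checks the search against an independent brute-force oracle to 1e-6
relative error.

The observed t-ratio is compared with t-ratios of voxel-permutation null
sets: each null map gets a fresh random permutation of its voxel order,
applied to *both* hemisphere maps before LI differencing. Applying one
permutation per map (rather than independent permutations per hemisphere)
matters: the bilateral background that the LI subtraction cancels in the
real data would otherwise survive into the null maps and inflate their
variance with structure the real statistic never sees, making the null
non-comparable. Each null set is run through the identical pipeline with
the retained-component count fixed to the real data's, and the add-one
permutation p-value is Bonferroni-corrected over the tested 2-D subspaces
(default: all 10 pairs of the first five dimensions).

Archetype maps are reconstructed by regressing each voxel's denoised
values on the embedding coordinates and evaluating the fit at the vertices
of the minimal enclosing triangle of the significant subspace (zeros for
dimensions outside it).

## Dominance and callosal connectivity

Hemispheric dominance of a voxel is `atan2(right, left) - pi/4` on the
component activation strengths, taken from the component with the largest
absolute z-score at that voxel — 0 for balanced activity, ±pi/4 for
unilateral activity, sign matching the LI convention (positive = right).
A component's strength in one hemisphere is the loading-weighted mean of
that hemisphere's activation values across terms (positive loadings as
weights: the terms that express the component), which keeps the strengths
non-negative as the arctangent definition requires.

Non-lateralised control regions are voxels that pass the same significance
machinery applied per hemisphere to the original (un-differenced) maps, in
both hemispheres at homologous locations, minus the lateralised voxels.
Connectivity is summarised by the probability of connection (fraction of
subjects with at least one streamline from the voxel to the corpus
callosum) and by the callosal axonal water fraction. Pool contrasts sample
5% of each pool without replacement, 1000 times, recording the difference
in mean connection probability and in replicability-weighted mean axonal
water fraction (a callosal voxel's weight is the fraction of subjects in
which it connects to a sampled voxel); repetitions in which no sampled
voxel connects in any subject have no defined weighted mean and are
reported as missing.

For the graded relationship, voxels are binned by connection probability
with geometric (ratio-2) bin edges anchored so the smallest bin width
equals the measurement resolution `1/n_subjects`; the top edge is capped
at 1, so widths double from bin to bin except possibly the final, capped
bin. Exact geometric spacing and an exact resolution-width first bin
cannot hold simultaneously unless the subject count is a power of two;
anchoring the first width at the resolution is the binding constraint.
The correlation between bin-mean absolute dominance and bin-mean
connection probability is Pearson's r over bins; the mean bilateral
activity `(left + right)/2` can be regressed out of both binned variables
first (partial correlation). A distance control pairs each lateralised
voxel with the non-lateralised voxel closest in distance to the
interhemispheric plane and correlates the per-pair connectivity difference
with distance.

## The synthetic generator

`generate_term_maps` plants everything the pipeline is supposed to find.
Archetype LI patterns are compact multi-focus networks (three signed
Gaussian foci, FWHM 10 mm), Gram-Schmidt-orthogonalised — archetypes are
maximally distinct specialised profiles — and standardised to zero mean
and unit sd over the half mask. Term weights are convex: roughly one term
in ten per archetype is a pure vertex term (families of closely related
terms), the rest Dirichlet(0.2), so the simplex is vertex-heavy. LI noise
has a white part (`noise_sd`, default 0.1) and a long tail of 80 weak
shared "minor networks" at 0.45 x `noise_sd`, emulating the slowly
decaying covariance spectrum of real map collections; without that tail
the grand-average rule retains exactly the planted rank and the
fixed-rank denoising makes even permutation nulls quasi-triangular. Both
noise parts vanish at `noise_sd = 0`, where every term map lies exactly
in the archetype simplex. The symmetric background is a standard-normal
mixture of three bilateral focus networks (amplitude 2, offset 5), which
gives the original maps the consistent bilateral structure that the
non-lateralised analysis needs. What the generator does *not* emulate:
realistic BOLD spatial autocorrelation beyond Gaussian smoothing,
non-Gaussian map marginals, anatomical asymmetries, or streamline
geometry — so passing tests certify the pipeline's statistical machinery,
not its behaviour on real acquisitions.

`generate_connectivity` plants a linear relation between connection
probability and absolute dominance, `p = p_base + conn_slope * |d|`,
clipped to `[1/n_subjects, 1]`, with per-subject Bernoulli indicators, and
an axonal-water-fraction offset for lateralised projections (one callosal
locus per cortical voxel). The defaults (`p_base = 0.6`,
`conn_slope = -3.2`) were calibrated once so that the *binned* correlation
at 2000 voxels and 163 subjects lands near -0.8, the regime the method is
meant to detect; with heavy clipping most voxels sit near the probability
floor, reproducing the small-probability-dominated distributions typical
of callosal connectivity data. A purely linear relation without clipping
is a poor test case: its bin means are collinear and the binned
correlation is always near -1 regardless of noise.

Exchangeable-hemisphere null volumes (`generate_null_maps`) share a
symmetric background with independent per-hemisphere noise and are used to
check the family-wise error of the significance test.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` run the whole chain at desk
scale: a 12x12x12 ellipsoid grid (456 homologous pairs), 60 terms, 3
archetypes, 500 permutations for the significance test, 200
voxel-permutation null sets for the triangularity test, 200 null datasets
for the family-wise-error calibration, 1000 repetitions for pool
contrasts, and 163 subjects for connectivity — sizes chosen so a complete
run takes minutes while every statistical property remains testable. All
randomness flows from one master seed through counter-based child seeds,
so identical configurations reproduce byte-identical reports.

## Known limitations

* The t-ratio test at 60 maps has modest resolution: the convex hull of a
  small point cloud is itself noisy, and individual realisations of the
  generator occasionally produce a real t-ratio in the low 0.9s that a
  long run of permutation nulls can graze.
* The minimal enclosing triangle search is numerical (grid + polish); its
  1e-6 agreement with the brute-force oracle is verified on hulls of up to
  8 vertices, the regime the embedding produces.
* Dominance uses component-level activation strengths at the
  argmax-|z| component; a raw-map-value mode is available but the
  component-level definition is the default.
* The per-hemisphere significance rerun that defines non-lateralised
  regions inherits all choices of the lateralisation test (beta maximum,
  20-voxel clusters); its voxel count is sensitive to the bilateral
  network amplitude of the data.
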