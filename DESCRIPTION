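Package: latmorph
Title: Functional Lateralisation Maps, Morphospace Embedding and Callosal
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing functional brain lateralisation from sets of
    volumetric activation maps registered to a left-right symmetric template.
    Computes voxelwise laterality-index (LI) maps, identifies significantly
    lateralised regions with a varimax-rotated principal component analysis
    and a rotation-aware maximal-statistic permutation test, embeds the LI
    maps in a low-dimensional morphospace by eigendecomposition of the
    normalised graph Laplacian of their similarity matrix, quantifies the
    triangularity of the embedded point cloud with a Pareto t-ratio test
    against voxel-permutation nulls, reconstructs archetype maps at simplex
    vertices, and relates graded hemispheric dominance to corpus-callosum
    connectivity. A synthetic-data generator with planted archetype and
    dominance-connectivity structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
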