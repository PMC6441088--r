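#' Component-denoise and embed an LI matrix
#'
#' Convenience wrapper chaining [fit_pca()], [rotate_model()],
#' [denoise_maps()], [similarity_matrix()] and [spectral_embed()] — the
#' shared trunk of the real-data and voxel-permutation-null analyses.
#'
#' @param li_matrix terms x voxels matrix.
#' @param n_retained fixed retained-component count, or `NULL` for the
#'   grand-average eigenvalue rule.
#' @param n_dims embedding dimensions to keep.
#' @return list with `model`, `denoised`, `embedding`.
#' @export
embed_pipeline <- function(li_matrix, n_retained = NULL, n_dims = 5) {
  model <- rotate_model(fit_pca(li_matrix, n_retained = n_retained))
  denoised <- denoise_maps(li_matrix, model)
  emb <- spectral_embed(similarity_matrix(denoised), n_dims = n_dims)
  list(model = model, denoised = denoised, embedding = emb)
}

#' Triangularity test against voxel-permutation null maps
#'
#' Computes the t-ratio of the embedded LI maps in each requested 2-D
#' subspace and compares it with t-ratios from null map sets in which the
#' voxel order of every map is permuted (a fresh permutation per map,
#' applied to both hemispheres before LI differencing, so the bilateral
#' background cancels in the nulls exactly as it does in the real LI maps
#' and only the spatial arrangement of lateralisation is destroyed). Each
#' null set is pushed through the identical pipeline — varimax component
#' analysis with the retained count fixed to the real data's, denoising,
#' similarity, spectral embedding — and its t-ratio recorded per subspace.
#' P-values use the add-one permutation estimator and are declared
#' significant after Bonferroni correction over the tested subspaces.
#'
#' @param halves list with `left` and `right` smoothed hemisphere matrices
#'   (terms x voxels), as from [hemisphere_matrices()].
#' @param dim_pairs 2-column matrix of dimension pairs to test; default all
#'   pairs among the first 5 embedding dimensions.
#' @param n_sets number of null sets (>= 50).
#' @param alpha family-wise significance level before Bonferroni.
#' @param seed integer seed for the null permutation stream.
#' @param n_dims embedding dimensions carried through the pipeline.
#' @param n_retained fixed component count; default: the real data's
#'   grand-average-rule count.
#' @return list of `t_ratio_result` objects (one per subspace, in
#'   `dim_pairs` order), each with `subspace`, `null_t_ratios`, `p_value`,
#'   `significant` (Bonferroni), plus attributes `real` (the real-data
#'   pipeline output) and `n_resampled` (null sets that failed and were
#'   redrawn).
#' @export
t_ratio_null_test <- function(halves, dim_pairs = NULL, n_sets = 200,
                              alpha = 0.05, seed = 1, n_dims = 5,
                              n_retained = NULL) {
  if (n_sets < 50) stop("'n_sets' must be >= 50")
  if (is.null(dim_pairs)) dim_pairs <- t(utils::combn(min(n_dims, 5), 2))
  dim_pairs <- matrix(as.integer(dim_pairs), ncol = 2)
  li <- halves$right - halves$left
  real <- embed_pipeline(li, n_retained = n_retained, n_dims = n_dims)
  k_fixed <- real$model$n_retained
  # real and null t-ratios share one (slightly coarser) search resolution;
  # only their comparison matters here
  tr_fast <- function(p) t_ratio(p, grid_step = pi / 60, n_polish = 3)
  real_t <- lapply(seq_len(nrow(dim_pairs)), function(i) {
    tr_fast(real$embedding$coords[, dim_pairs[i, ]])
  })
  nv <- ncol(li)
  nt <- nrow(li)
  null_t <- matrix(NA_real_, n_sets, nrow(dim_pairs))
  set.seed(seed)
  n_resampled <- 0L
  s <- 1L
  while (s <= n_sets) {
    Lp <- halves$left
    Rp <- halves$right
    for (t in seq_len(nt)) {
      prm <- sample.int(nv)
      Lp[t, ] <- Lp[t, prm]
      Rp[t, ] <- Rp[t, prm]
    }
    ok <- try({
      pl <- embed_pipeline(Rp - Lp, n_retained = k_fixed, n_dims = n_dims)
      for (i in seq_len(nrow(dim_pairs))) {
        null_t[s, i] <- tr_fast(pl$embedding$coords[, dim_pairs[i, ]])$t_ratio
      }
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      n_resampled <- n_resampled + 1L
      if (n_resampled > n_sets) stop("too many null pipeline failures")
      next
    }
    s <- s + 1L
  }
  n_tests <- nrow(dim_pairs)
  out <- lapply(seq_len(n_tests), function(i) {
    r <- real_t[[i]]
    r$subspace <- dim_pairs[i, ]
    r$null_t_ratios <- null_t[, i]
    r$p_value <- (1 + sum(null_t[, i] >= r$t_ratio)) / (1 + n_sets)
    r$significant <- r$p_value < alpha / n_tests
    r
  })
  attr(out, "real") <- real
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Plot an embedded 2-D subspace with its minimal enclosing triangle
#'
#' Scatter of the embedded maps in one 2-D subspace with the convex hull
#' and the minimal enclosing triangle overlaid; written as an SVG file if a
#' path is given, otherwise drawn on the current device.
#'
#' @param coords maps x dims coordinate matrix.
#' @param tr a [t_ratio()] result for the plotted subspace.
#' @param subspace integer pair of dimensions to plot.
#' @param file optional path of an SVG file.
#' @return the file path (or `NULL` when drawn on the current device),
#'   invisibly.
#' @export
plot_embedding <- function(coords, tr, subspace = c(1L, 2L), file = NULL) {
  P <- coords[, subspace, drop = FALSE]
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 6)
    on.exit(grDevices::dev.off())
  }
  V <- tr$triangle_vertices
  xl <- range(c(P[, 1], V[, 1])); yl <- range(c(P[, 2], V[, 2]))
  plot(P, xlab = paste0("dim ", subspace[1]), ylab = paste0("dim ", subspace[2]),
       pch = 19, cex = 0.7, col = "grey30", xlim = xl, ylim = yl,
       main = sprintf("t-ratio = %.3f", tr$t_ratio), asp = 1)
  h <- grDevices::chull(P)
  graphics::polygon(P[h, 1], P[h, 2], border = "steelblue", lwd = 1.5)
  graphics::polygon(V[, 1], V[, 2], border = "firebrick", lwd = 1.5, lty = 2)
  graphics::points(V, pch = 17, col = "firebrick", cex = 1.2)
  invisible(file)
}

#' Archetype maps at simplex vertices
#'
#' Regresses each voxel's values across the denoised LI maps onto the maps'
#' embedding coordinates (first `n_regress_dims` dimensions plus an
#' intercept) and evaluates the fitted linear model at the supplied vertex
#' coordinates, with zeros for every dimension outside the tested subspace.
#'
#' @param denoised maps x voxels matrix.
#' @param coords maps x dims embedding coordinates.
#' @param vertices 3 x 2 matrix of vertex coordinates in the tested
#'   subspace (e.g. `triangle_vertices` of a [t_ratio()] result).
#' @param subspace integer pair: which embedding dimensions the vertex
#'   coordinates refer to.
#' @param n_regress_dims how many embedding dimensions enter the
#'   regression (<= `ncol(coords)`).
#' @return list of archetype maps, each a list with `vertex_coords` (in the
#'   subspace), `predicted_li` (voxel vector), `label`.
#' @export
archetype_maps <- function(denoised, coords, vertices, subspace = c(1L, 2L),
                           n_regress_dims = ncol(coords)) {
  if (n_regress_dims > ncol(coords)) {
    stop("'n_regress_dims' exceeds available embedding dimensions")
  }
  X <- cbind(1, coords[, seq_len(n_regress_dims), drop = FALSE])
  coef <- qr.coef(qr(X), denoised)
  bb <- apply(coords[, subspace, drop = FALSE], 2, range)
  span <- bb[2, ] - bb[1, ]
  lapply(seq_len(nrow(vertices)), function(i) {
    v <- vertices[i, ]
    if (any(v < bb[1, ] - 0.5 * span | v > bb[2, ] + 0.5 * span)) {
      warning("vertex ", i, " lies far outside the fitted coordinate range",
              " (extrapolation)")
    }
    x <- numeric(n_regress_dims)
    x[subspace] <- v
    list(vertex_coords = v,
         predicted_li = drop(c(1, x) %*% coef),
         label = paste0("archetype", i))
  })
}
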