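#' Denoise LI maps by component reconstruction
#'
#' Reconstructs every LI map as the matrix product of its rotated component
#' loadings and the component spatial (beta) maps, with the per-voxel
#' intercept re-added — i.e. keeps only the variance captured by the
#' retained components.
#'
#' @param li_matrix terms x voxels matrix the model was fitted on.
#' @param model a rotated [fit_pca()] model.
#' @return terms x voxels matrix of denoised LI maps.
#' @export
denoise_maps <- function(li_matrix, model) {
  if (is.null(model$rotated)) model <- rotate_model(model)
  g <- spatial_maps_glm(li_matrix, model$rotated)
  if (ncol(g$betas) != ncol(li_matrix)) stop("dimension mismatch")
  D <- g$fitted    # loadings %*% betas plus the orthogonalised mean term
  dimnames(D) <- dimnames(li_matrix)
  D
}

#' Dot-product similarity matrix of denoised LI maps
#'
#' Entry (i, j) is the dot product of maps i and j across voxels, with
#' negative values zeroed (a similarity graph needs non-negative weights)
#' and the diagonal set to zero (self-similarity carries no graph
#' structure).
#'
#' @param denoised maps x voxels matrix (>= 3 maps).
#' @return maps x maps non-negative symmetric matrix with zero diagonal.
#' @export
similarity_matrix <- function(denoised) {
  X <- as.matrix(denoised)
  if (nrow(X) < 3) stop("need at least 3 maps")
  S <- X %*% t(X)
  S[S < 0] <- 0
  diag(S) <- 0
  if (all(S == 0)) stop("similarity matrix is all zero: no graph")
  S
}

#' Spectral embedding via the normalised graph Laplacian
#'
#' Eigendecomposition of the symmetric normalised Laplacian
#' `L = I - D^(-1/2) W D^(-1/2)` of the similarity graph `W`. Eigenvalues
#' are sorted ascending (all in \[0, 2\]); the first, zero-eigenvalue
#' dimension is non-informative and dropped. Coordinates are the
#' degree-rescaled eigenvectors `D^(-1/2) u` of dimensions 2..n_dims+1,
#' with each dimension's sign fixed so its largest-magnitude entry is
#' positive.
#'
#' @param similarity non-negative symmetric matrix with zero diagonal; its
#'   graph must be connected.
#' @param n_dims number of embedding dimensions to keep
#'   (`< nrow(similarity)`).
#' @return object of class `embedding_space`: list with `coords`
#'   (maps x n_dims), `eigenvalues` (all, ascending), `similarity`.
#' @export
spectral_embed <- function(similarity, n_dims = 5) {
  W <- as.matrix(similarity)
  n <- nrow(W)
  if (n_dims >= n) stop("'n_dims' must be smaller than the number of maps")
  if (any(W < 0)) stop("similarity must be non-negative")
  ncomp <- graph_components(W > 0)
  if (ncomp > 1) {
    stop("similarity graph is disconnected (", ncomp, " components)")
  }
  d <- rowSums(W)
  dinv <- 1 / sqrt(d)
  Lsym <- diag(n) - (dinv %o% dinv) * W
  e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  ev <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  # repeated eigenvalues leave within-eigenspace rotation arbitrary
  if (any(diff(ev[seq_len(n_dims + 1)]) < 1e-10)) {
    message("near-degenerate Laplacian eigenvalues among embedded dimensions")
  }
  coords <- dinv * U[, 2:(n_dims + 1), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(W)
  colnames(coords) <- paste0("dim", seq_len(n_dims))
  structure(list(coords = coords, eigenvalues = ev, similarity = W),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("<embedding_space> ", nrow(x$coords), " maps in ", ncol(x$coords),
      " dimensions; leading eigenvalues: ",
      paste(signif(x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))], 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# number of connected components of an undirected adjacency matrix
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}
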