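#' Principal component analysis of an LI matrix
#'
#' Eigendecomposition of the term-by-term covariance matrix, with terms as
#' variables and voxels as observations (each term's LI values are centred
#' across voxels). Components are retained by the grand-average rule:
#' eigenvalues strictly greater than the mean eigenvalue.
#'
#' @param li_matrix terms x voxels matrix (>= 3 terms).
#' @param n_retained optional fixed number of retained components,
#'   overriding the grand-average rule (used by null pipelines that must
#'   match the real data's component count).
#' @return object of class `component_model`: `loadings` (term x component,
#'   unrotated, all components), `eigenvalues`, `n_retained`,
#'   `variance_explained`, `center` (per-voxel nothing; centring is per
#'   term), plus rotated fields once [rotate_model()] is applied.
#' @export
fit_pca <- function(li_matrix, n_retained = NULL) {
  X <- as.matrix(li_matrix)
  if (nrow(X) < 3) stop("need at least 3 terms for a component analysis")
  Xc <- X - rowMeans(X)
  C <- Xc %*% t(Xc) / (ncol(X) - 1)
  if (max(abs(C)) == 0) stop("rank-0 data: all LI maps are constant")
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  k <- if (is.null(n_retained)) sum(ev > mean(ev)) else as.integer(n_retained)
  if (k < 1) stop("no components retained")
  structure(list(
    loadings = e$vectors,
    eigenvalues = ev,
    n_retained = k,
    variance_explained = sum(ev[seq_len(k)]) / sum(ev),
    term_means = rowMeans(X)
  ), class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat("<component_model> ", length(x$eigenvalues), " terms, ",
      x$n_retained, " retained components (",
      round(100 * x$variance_explained, 1), "% variance)\n", sep = "")
  if (!is.null(x$rotated)) cat("  varimax-rotated (Kaiser normalisation)\n")
  invisible(x)
}

#' Varimax rotation with Kaiser normalisation
#'
#' Orthogonal rotation maximising the varimax criterion (sum over components
#' of the variance of squared loadings) after rescaling each row of the
#' loading matrix to unit length (Kaiser normalisation), undone after
#' rotation. Uses the standard SVD-based iteration; the criterion is
#' monotonically non-decreasing across iterations and the rotation matrix is
#' orthogonal by construction.
#'
#' @param loadings term x component matrix, >= 2 columns.
#' @param max_iter maximum iterations (default 1000).
#' @param tol convergence tolerance on the relative criterion change
#'   (default 1e-6).
#' @return list with `rotated` (loadings after rotation, Kaiser scaling
#'   restored), `rotation_matrix` (orthogonal), `converged`, `iterations`,
#'   `criterion` (trace of the varimax criterion of the normalised
#'   loadings).
#' @export
varimax_kaiser <- function(loadings, max_iter = 1000, tol = 1e-6) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 2) {
    return(list(rotated = L, rotation_matrix = diag(1), converged = TRUE,
                iterations = 0L, criterion = varimax_criterion(L)))
  }
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  Z0 <- L / h
  eng <- .varimax_engine(Z0, as.integer(max_iter), tol)
  if (!eng$converged) {
    warning("varimax did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  R <- eng$rotation
  list(rotated = (Z0 %*% R) * h, rotation_matrix = R,
       converged = eng$converged, iterations = eng$iterations,
       criterion = eng$criterion)
}

# varimax simplicity criterion: sum over components of the variance of
# squared loadings
varimax_criterion <- function(Z) {
  Z2 <- Z^2
  sum(colMeans(Z2^2) - colMeans(Z2)^2)
}

#' Apply varimax rotation to the retained components of a model
#'
#' @param model a [fit_pca()] result.
#' @param max_iter,tol passed to [varimax_kaiser()].
#' @return the model with fields `rotated` (term x retained loadings),
#'   `rotation_matrix`, `varimax_converged` added, and `labels` (top
#'   loading term per component) if the LI matrix had rownames.
#' @export
rotate_model <- function(model, max_iter = 1000, tol = 1e-6) {
  Lr <- model$loadings[, seq_len(model$n_retained), drop = FALSE]
  v <- varimax_kaiser(Lr, max_iter = max_iter, tol = tol)
  # column sign convention: the largest-magnitude loading is positive
  for (j in seq_len(ncol(v$rotated))) {
    i <- which.max(abs(v$rotated[, j]))
    if (v$rotated[i, j] < 0) {
      v$rotated[, j] <- -v$rotated[, j]
      v$rotation_matrix[, j] <- -v$rotation_matrix[, j]
    }
  }
  model$rotated <- v$rotated
  model$rotation_matrix <- v$rotation_matrix
  model$varimax_converged <- v$converged
  if (!is.null(rownames(model$rotated))) {
    model$labels <- rownames(model$rotated)[apply(abs(model$rotated), 2, which.max)]
  }
  model
}

#' Voxelwise GLM spatial maps for component loadings
#'
#' Ordinary least squares of every voxel's across-term LI vector on the
#' rotated component loadings, with an intercept term orthogonalised
#' against the loadings. Giving the loadings priority keeps their
#' coefficients identical to the no-intercept projection (for orthonormal
#' loadings, `beta = t(L) %*% y`) and keeps the fit well conditioned even
#' when the loading span contains (or nearly contains) the constant term
#' vector — which happens whenever the term profiles are convex mixtures of
#' a few patterns. The orthogonalised intercept direction still absorbs any
#' residual mean, so fitted values (used for denoising) include it. When
#' the constant vector lies exactly in the loading span the intercept
#' column is dropped as redundant.
#'
#' @param li_matrix terms x voxels matrix.
#' @param loadings term x component predictor matrix (full column rank).
#' @return list with `betas` (component x voxel), `z` (component x voxel,
#'   beta / SE), `fitted` (terms x voxels), `sigma2` (per-voxel residual
#'   variance).
#' @export
spatial_maps_glm <- function(li_matrix, loadings) {
  Y <- as.matrix(li_matrix)
  L <- as.matrix(loadings)
  k <- ncol(L)
  ql <- qr(L)
  if (ql$rank < k) {
    stop("predictor matrix is rank deficient (columns ",
         paste(setdiff(seq_len(k), seq_len(ql$rank)), collapse = ", "),
         " of the loadings are collinear)")
  }
  e1 <- qr.resid(ql, rep(1, nrow(L)))
  has_int <- sqrt(sum(e1^2)) > 1e-8 * sqrt(nrow(L))
  X <- if (has_int) cbind(L, e1 / sqrt(sum(e1^2))) else L
  qx <- qr(X)
  coef <- qr.coef(qx, Y)
  fitted <- X %*% coef
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / max(df, 1)
  d <- diag(chol2inv(qr.R(qx)))
  betas <- coef[seq_len(k), , drop = FALSE]
  se <- sqrt(outer(d[seq_len(k)], sigma2))
  z <- betas / se
  z[se == 0] <- 0
  list(betas = betas, z = z, fitted = fitted, sigma2 = sigma2)
}

# one permutation replicate of the rotation-aware max-statistic null:
# permute the rows of the unrotated retained loadings, re-rotate, refit
perm_stat_extrema <- function(li_matrix, unrotated_retained, perm, statistic) {
  Lp <- unrotated_retained[perm, , drop = FALSE]
  v <- suppressWarnings(varimax_kaiser(Lp))
  if (statistic == "beta") {
    # loading betas in the orthogonalised-intercept design equal the
    # plain projection coefficients (the extra column is orthogonal)
    co <- qr.coef(qr(v$rotated), li_matrix)
    c(min(co), max(co))
  } else {
    g <- spatial_maps_glm(li_matrix, v$rotated)
    c(min(g$z), max(g$z))
  }
}

#' Rotation-aware maximal-statistic permutation significance test
#'
#' Identifies voxels with a significantly lateralised spatial-map value for
#' any retained component. On each permutation the rows of the *unrotated*
#' retained loading matrix are permuted, varimax is re-applied (so the null
#' reproduces the correlational structure that rotation can induce), the
#' voxelwise GLM is refit, and the single largest and smallest beta across
#' the whole map are recorded. A real beta is significant when it is larger
#' (strictly) than a fraction `1 - alpha/2` of the permutation maxima, or
#' smaller than a fraction `1 - alpha/2` of the minima, and belongs to a
#' connected cluster of at least `cluster_min` voxels of same-sign
#' significant voxels for the same component.
#'
#' @param li_matrix terms x voxels matrix used to fit `model`.
#' @param model a rotated [fit_pca()] model (see [rotate_model()]).
#' @param n_perm number of permutations (>= 100 and large enough for
#'   `alpha`).
#' @param alpha two-tailed family-wise error level in (0, 0.5).
#' @param cluster_min minimum surviving cluster size in voxels (default 20).
#' @param connectivity neighbourhood for clustering: 6, 18 or 26 (default
#'   26, face+edge+corner).
#' @param statistic map statistic entering the maximal-statistic
#'   comparison: `"beta"` (default; raw GLM spatial-map values) or `"z"`
#'   (beta / SE). The beta maximum is exchangeable under loading-row
#'   permutation and calibrates on null data; the z maximum inherits the
#'   anti-conservative alignment between data-derived components and their
#'   own residual variance and is provided for exploration only.
#' @param seed integer seed for the permutation stream.
#' @param grid the grid the voxel columns live on (needed for clustering);
#'   defaults to `attr(li_matrix, "grid")`.
#' @return object of class `significance_mask`: list with `pos`/`neg`
#'   (component x voxel logical matrices after cluster filtering), `any`
#'   (voxel logical, any component/sign), `maxima`/`minima` (null samples),
#'   `thresholds`, `alpha`, `cluster_min`, `n_significant_components`.
#' @export
permutation_significance <- function(li_matrix, model, n_perm = 1000,
                                     alpha = 0.05, cluster_min = 20,
                                     connectivity = 26,
                                     statistic = c("beta", "z"), seed = 1,
                                     grid = attr(li_matrix, "grid")) {
  statistic <- match.arg(statistic)
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must be in (0, 0.5)")
  if (n_perm < 100) stop("'n_perm' must be >= 100")
  if (n_perm * alpha / 2 < 1) {
    stop("n_perm = ", n_perm, " is too small for alpha = ", alpha)
  }
  if (is.null(grid)) stop("a 'lat_grid' is required for cluster filtering")
  if (is.null(model$rotated)) model <- rotate_model(model)
  Lr <- model$loadings[, seq_len(model$n_retained), drop = FALSE]
  g <- spatial_maps_glm(li_matrix, model$rotated)
  n_terms <- nrow(Lr)
  set.seed(seed)
  extrema <- vapply(seq_len(n_perm), function(i) {
    perm_stat_extrema(li_matrix, Lr, sample.int(n_terms), statistic)
  }, numeric(2))
  minima <- extrema[1, ]
  maxima <- extrema[2, ]
  # strict inequality against at least (1 - alpha/2) of the null extrema
  n_hi <- ceiling((1 - alpha / 2) * n_perm)
  thr_hi <- sort(maxima)[n_hi]
  thr_lo <- sort(minima, decreasing = TRUE)[n_hi]
  stat <- if (statistic == "z") g$z else g$betas
  pos <- stat > thr_hi
  neg <- stat < thr_lo
  hm <- half_mask(grid)
  hi <- which(hm)
  for (cc in seq_len(nrow(pos))) {
    pos[cc, ] <- filter_cluster_row(pos[cc, ], hm, hi, connectivity, cluster_min)
    neg[cc, ] <- filter_cluster_row(neg[cc, ], hm, hi, connectivity, cluster_min)
  }
  structure(list(
    pos = pos, neg = neg, any = apply(pos | neg, 2, any),
    maxima = maxima, minima = minima,
    thresholds = c(lower = thr_lo, upper = thr_hi),
    alpha = alpha, cluster_min = cluster_min, connectivity = connectivity,
    statistic = statistic,
    n_significant_components = sum(apply(pos | neg, 1, any)),
    betas = g$betas, z = g$z, intercept = g$intercept
  ), class = "significance_mask")
}

filter_cluster_row <- function(sel, hm, hi, connectivity, cluster_min) {
  if (!any(sel)) return(sel)
  vol <- array(FALSE, dim(hm))
  vol[hi[sel]] <- TRUE
  lab <- label_clusters(vol, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab[hi] > 0 & sizes[pmax(lab[hi], 1)] >= cluster_min
  sel & keep
}

#' Label connected clusters in a 3-D logical array
#'
#' Breadth-first connected-component labelling under a 6 (face), 18
#' (face+edge) or 26 (face+edge+corner) neighbourhood.
#'
#' @param vol logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same shape; 0 outside `vol`, cluster ids
#'   1..n inside.
#' @export
label_clusters <- function(vol, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  d <- dim(vol)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  lab <- array(0L, d)
  ids <- which(vol)
  nextlab <- 0L
  for (s in ids) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    queue <- s
    lab[s] <- nextlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      nb <- sweep(off, 2, ci, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[vol[lin] & lab[lin] == 0L]
      lab[lin] <- nextlab
      queue <- c(queue, lin)
    }
  }
  lab
}
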