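# build a terms x voxels matrix with prescribed term-covariance eigenvalues
make_data_with_eigenvalues <- function(ev, n_vox, seed = 1) {
  set.seed(seed)
  t_ <- length(ev)
  U <- qr.Q(qr(matrix(rnorm(t_ * t_), t_)))
  # row-centred scores, orthonormalised so the sample covariance is exact
  S <- matrix(rnorm(t_ * n_vox), t_)
  S <- S - rowMeans(S)
  S <- t(qr.Q(qr(t(S))))
  U %*% diag(sqrt(ev * (n_vox - 1))) %*% S
}

test_that("grand-average retention rule and variance bookkeeping", {
  X <- make_data_with_eigenvalues(c(3, 1, 0.5, 0.5), 200)
  m <- fit_pca(X)
  expect_equal(m$eigenvalues[1:4], c(3, 1, 0.5, 0.5), tolerance = 1e-8)
  # mean eigenvalue 1.25 -> only the first retained, 3/5 of the variance
  expect_equal(m$n_retained, 1)
  expect_equal(m$variance_explained, 0.6, tolerance = 1e-8)
})

test_that("rank-K data yield exactly K nonzero eigenvalues and exact
           reconstruction from all components", {
  set.seed(6)
  W <- matrix(runif(20 * 3), 20)
  A <- matrix(rnorm(3 * 300), 3)
  X <- W %*% A
  m <- fit_pca(X)
  expect_equal(sum(m$eigenvalues > 1e-10 * m$eigenvalues[1]), 3)

  set.seed(7)
  Y <- matrix(rnorm(20 * 500), 20)
  mf <- fit_pca(Y)
  Yc <- Y - rowMeans(Y)
  scores <- t(mf$loadings) %*% Yc
  expect_equal(mf$loadings %*% scores, Yc, tolerance = 1e-10)

  expect_error(fit_pca(Y[1:2, ]), "at least 3")
  expect_error(fit_pca(matrix(1, 5, 10)), "rank-0")
})

test_that("varimax keeps the loading geometry and improves the criterion", {
  set.seed(8)
  L <- matrix(rnorm(30 * 4), 30)
  v <- varimax_kaiser(L)
  expect_equal(crossprod(v$rotation_matrix), diag(4), tolerance = 1e-10)
  expect_equal(tcrossprod(v$rotated), tcrossprod(L), tolerance = 1e-8)
  expect_false(is.unsorted(v$criterion))

  # a perfectly simple structure is a varimax fixed point (up to column
  # sign and order)
  Ls <- diag(c(2, 1.5, 1))[rep(1:3, each = 5), ]
  vs <- varimax_kaiser(Ls)
  expect_equal(abs(vs$rotated[abs(vs$rotated) > 1e-8]),
               abs(Ls[Ls != 0]), tolerance = 1e-6)

  # independent check against the base-R implementation
  ref <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
  crit_mine <- latmorph:::varimax_criterion(v$rotated / sqrt(rowSums(L^2)))
  crit_ref <- latmorph:::varimax_criterion(
    unclass(ref$loadings) / sqrt(rowSums(L^2)))
  expect_equal(crit_mine, crit_ref, tolerance = 1e-4)
})

test_that("two-column varimax matches an exhaustive rotation-angle sweep", {
  set.seed(9)
  L <- matrix(rnorm(24 * 2), 24)
  h <- sqrt(rowSums(L^2))
  angles <- seq(0, pi / 2, by = 0.01 * pi / 180)
  crits <- vapply(angles, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    latmorph:::varimax_criterion((L / h) %*% R)
  }, numeric(1))
  v <- varimax_kaiser(L, tol = 1e-12)
  expect_gte(latmorph:::varimax_criterion(v$rotated / h) + 1e-9, max(crits))
})

test_that("voxelwise GLM recovers exact linear structure", {
  set.seed(10)
  L <- qr.Q(qr(matrix(rnorm(25 * 3), 25)))   # orthonormal loadings
  patt <- matrix(rnorm(3 * 100), 3)
  Y <- L %*% patt
  g <- spatial_maps_glm(Y, L)
  expect_equal(g$betas, patt, tolerance = 1e-8)

  # orthonormal columns: beta is the plain column projection
  Y2 <- Y + matrix(rnorm(25 * 100, sd = 0.2), 25)
  g2 <- spatial_maps_glm(Y2, L)
  expect_equal(g2$betas, t(L) %*% Y2, tolerance = 1e-10)

  # all-zero voxel -> zero betas and z
  Y3 <- cbind(Y2, 0)
  g3 <- spatial_maps_glm(Y3, L)
  expect_equal(g3$betas[, 101], rep(0, 3))
  expect_equal(g3$z[, 101], rep(0, 3))

  expect_error(spatial_maps_glm(Y, cbind(L, L[, 1])), "rank deficient")
})

test_that("cluster labelling respects the chosen neighbourhood", {
  vol <- array(FALSE, c(6, 6, 6))
  vol[1:2, 1:2, 1] <- TRUE          # 4-voxel blob
  vol[4, 4, 2] <- TRUE              # corner-touching second blob seed
  vol[3, 3, 1] <- TRUE              # touches blob 1 only diagonally
  lab6 <- label_clusters(vol, 6)
  lab18 <- label_clusters(vol, 18)
  lab26 <- label_clusters(vol, 26)
  expect_equal(max(lab6), 3)        # face connectivity splits all three
  expect_equal(max(lab18), 2)       # edge connectivity joins the in-plane
                                    # diagonal but not the 3-D corner
  expect_equal(max(lab26), 1)       # corner connectivity joins everything
  expect_error(label_clusters(vol, 10), "6, 18 or 26")
})

test_that("clusters below the minimum size are removed", {
  g <- tiny_grid(c(10, 10, 10), "box")
  hm <- half_mask(g)
  hi <- which(hm)
  sel <- rep(FALSE, length(hi))
  ijk <- which(hm, arr.ind = TRUE)
  blob <- which(ijk[, 1] <= 3 & ijk[, 2] <= 3 & ijk[, 3] <= 3)[1:19]
  sel[blob] <- TRUE
  expect_equal(sum(latmorph:::filter_cluster_row(sel, hm, hi, 26, 20)), 0)
  sel[which(ijk[, 1] <= 3 & ijk[, 2] <= 3 & ijk[, 3] <= 3)[20]] <- TRUE
  expect_equal(sum(latmorph:::filter_cluster_row(sel, hm, hi, 26, 20)), 20)
})

test_that("permutation test recovers a strong planted single component", {
  grid <- make_symmetric_grid(c(12, 12, 12), "ellipsoid")
  hm <- half_mask(grid)
  ijk <- which(hm, arr.ind = TRUE)
  ctr <- c(3, 6, 6)
  patt <- ifelse(rowSums(sweep(ijk, 2, ctr)^2) <= 6, 3, 0)
  set.seed(42)
  li <- outer(rnorm(30), patt) + matrix(rnorm(30 * nrow(ijk), sd = 0.3), 30)
  attr(li, "grid") <- grid
  m <- rotate_model(fit_pca(li))
  sig <- permutation_significance(li, m, n_perm = 300, seed = 5, grid = grid)
  expect_gte(sum(sig$any & patt > 0) / sum(patt > 0), 0.9)
  expect_equal(sum(sig$any & patt == 0), 0)

  expect_error(permutation_significance(li, m, n_perm = 50, grid = grid),
               ">= 100")
  expect_error(permutation_significance(li, m, n_perm = 300, alpha = 0.6,
                                        grid = grid), "alpha")
  expect_error(permutation_significance(li, m, n_perm = 100, alpha = 0.01,
                                        grid = grid), "too small")
})

test_that("reordering terms permutes loadings without changing the fit", {
  ps <- planted_set()
  li <- ps$li
  set.seed(12)
  perm <- sample(nrow(li))
  m1 <- fit_pca(li)
  m2 <- fit_pca(li[perm, ])
  expect_equal(m2$eigenvalues, m1$eigenvalues, tolerance = 1e-8)
  k <- m1$n_retained
  for (j in seq_len(k)) {
    expect_equal(abs(m2$loadings[, j]), abs(m1$loadings[perm, j]),
                 tolerance = 1e-6)
  }
})
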