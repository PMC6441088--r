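#' Mask-renormalised Gaussian smoothing of a hemisphere half
#'
#' Separable 3-D Gaussian convolution with per-axis standard deviation
#' `fwhm_mm / (2 * sqrt(2 * log(2)))` (in voxels after dividing by the voxel
#' size), truncated at 4 sd. The kernel is renormalised within the mask:
#' values outside the mask carry no weight and the local kernel mass is
#' rescaled to one, so a constant field is reproduced exactly and no signal
#' leaks across mask edges (in particular, halves are smoothed separately so
#' nothing crosses the midline).
#'
#' @param half 3-D array on the half grid.
#' @param fwhm_mm full width at half maximum of the Gaussian, millimetres.
#'   Zero returns the input unchanged (masked).
#' @param voxel_size_mm voxel edge length, millimetres.
#' @param mask logical half-grid array; smoothing is confined to it.
#' @return smoothed half-grid array, zero outside the mask.
#' @export
smooth_gaussian <- function(half, fwhm_mm, voxel_size_mm, mask) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be non-negative")
  stopifnot(all(dim(half) == dim(mask)))
  m <- array(as.numeric(mask), dim = dim(mask))
  x <- half * m
  if (fwhm_mm == 0) return(x)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  num <- conv_gauss3(x, sd_vox)
  den <- conv_gauss3(m, sd_vox)
  out <- array(0, dim = dim(half))
  out[mask] <- num[mask] / den[mask]
  out
}

# 1-D Gaussian kernel, truncated at 4 sd, unit mass
gauss_kernel <- function(sd_vox) {
  r <- max(1L, ceiling(4 * sd_vox))
  k <- exp(-0.5 * ((-r):r / sd_vox)^2)
  k / sum(k)
}

# separable 3-D convolution via dense banded matrices (grids are small)
conv_gauss3 <- function(arr, sd_vox) {
  k <- gauss_kernel(sd_vox)
  r <- (length(k) - 1L) / 2L
  d <- dim(arr)
  conv_mat <- function(n) {
    A <- matrix(0, n, n)
    for (off in (-r):r) {
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      A[cbind(i[ok], j[ok])] <- A[cbind(i[ok], j[ok])] + k[off + r + 1L]
    }
    A
  }
  # axis 1
  x <- matrix(arr, d[1], d[2] * d[3])
  x <- conv_mat(d[1]) %*% x
  arr <- array(x, d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  x <- matrix(arr, d[2], d[1] * d[3])
  x <- conv_mat(d[2]) %*% x
  arr <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 2, 1))
  x <- matrix(arr, d[3], d[2] * d[1])
  x <- conv_mat(d[3]) %*% x
  aperm(array(x, d[c(3, 2, 1)]), c(3, 2, 1))
}

#' Laterality-index map of one volume
#'
#' Splits the volume into hemisphere halves, smooths each half within the
#' half mask, then subtracts the (already flipped) left half from the right
#' half. Positive values mean stronger right-hemisphere activation.
#'
#' @param volume 3-D array on the symmetric grid.
#' @param grid a [make_symmetric_grid()] object.
#' @param fwhm_mm Gaussian smoothing FWHM in mm applied to each half
#'   (default 6, a standard choice for 2 mm voxel grids).
#' @param term optional label carried along.
#' @return object of class `li_map`: list with `values` (half-grid array,
#'   zero outside the half mask), `term`, `fwhm_mm`.
#' @export
compute_li <- function(volume, grid, fwhm_mm = 6, term = NULL) {
  hs <- split_hemispheres(volume, grid)
  hm <- half_mask(grid)
  rs <- smooth_gaussian(hs$right, fwhm_mm, grid$voxel_size_mm, hm)
  ls <- smooth_gaussian(hs$left, fwhm_mm, grid$voxel_size_mm, hm)
  structure(list(values = rs - ls, term = term, fwhm_mm = fwhm_mm),
            class = "li_map")
}

#' Laterality-index matrix of a term-map set
#'
#' Applies [compute_li()] to every term volume and stacks the in-mask
#' half-grid values into a terms x voxels matrix, the input to the component
#' analysis.
#'
#' @param maps a `term_maps` object (see [generate_term_maps()] or
#'   [read_volumes()]).
#' @param fwhm_mm smoothing FWHM in mm.
#' @return matrix (terms x half-mask voxels) with term labels as rownames;
#'   attributes `grid` and `fwhm_mm`.
#' @export
li_matrix <- function(maps, fwhm_mm = 6) {
  grid <- maps$grid
  hi <- half_indices(grid)
  out <- matrix(0, nrow = length(maps$terms), ncol = length(hi),
                dimnames = list(maps$terms, NULL))
  for (t in seq_along(maps$terms)) {
    li <- compute_li(maps$volumes[[t]], grid, fwhm_mm)
    out[t, ] <- li$values[hi]
  }
  attr(out, "grid") <- grid
  attr(out, "fwhm_mm") <- fwhm_mm
  out
}

#' Smoothed hemisphere-half matrices of a term-map set
#'
#' Same preprocessing as [li_matrix()] but keeping the two smoothed halves
#' separate (needed by the voxel-permutation null of the triangularity test,
#' which permutes hemisphere maps before LI differencing, and by the
#' per-hemisphere significance analysis of the original maps).
#'
#' @inheritParams li_matrix
#' @return list with matrices `left`, `right` (terms x half-mask voxels) and
#'   the `grid`.
#' @export
hemisphere_matrices <- function(maps, fwhm_mm = 6) {
  grid <- maps$grid
  hm <- half_mask(grid)
  hi <- which(hm)
  L <- R <- matrix(0, nrow = length(maps$terms), ncol = length(hi),
                   dimnames = list(maps$terms, NULL))
  for (t in seq_along(maps$terms)) {
    hs <- split_hemispheres(maps$volumes[[t]], grid)
    L[t, ] <- smooth_gaussian(hs$left, fwhm_mm, grid$voxel_size_mm, hm)[hi]
    R[t, ] <- smooth_gaussian(hs$right, fwhm_mm, grid$voxel_size_mm, hm)[hi]
  }
  list(left = L, right = R, grid = grid, fwhm_mm = fwhm_mm)
}
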