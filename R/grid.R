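#' Symmetric analysis grid
#'
#' A `lat_grid` describes a 3-D voxel grid whose left and right hemispheres
#' are mirror images of each other across one axis (the analogue of a
#' left-right symmetric template). There is no shared midline voxel: the
#' extent along the mirror axis must be even, so every voxel has exactly one
#' homologue in the opposite hemisphere.
#'
#' Indexing convention: along the mirror axis, slabs `1..n/2` are the left
#' hemisphere and `n/2+1..n` the right. Half-grid arrays are indexed by the
#' distance `h = 1..n/2` from the midline, so that equal half-grid indices
#' always refer to homologous voxel pairs (the left half is stored already
#' flipped).
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param mask_kind `"box"` (every voxel in-brain) or `"ellipsoid"`
#'   (inscribed ellipsoid, a crude brain-like mask).
#' @param mirror_axis axis index (1..3) across which hemispheres mirror.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @return an object of class `lat_grid` with fields `shape`, `mirror_axis`,
#'   `mask` (logical 3-D array, exactly mirror-symmetric), `voxel_size_mm`.
#' @examples
#' g <- make_symmetric_grid(c(8, 8, 8), "ellipsoid")
#' sum(g$mask)
#' @export
make_symmetric_grid <- function(shape, mask_kind = c("box", "ellipsoid"),
                                mirror_axis = 1L, voxel_size_mm = 2) {
  mask_kind <- match.arg(mask_kind)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    stop("'shape' must be three integers, each >= 4")
  }
  if (!mirror_axis %in% 1:3) stop("'mirror_axis' must be 1, 2 or 3")
  if (shape[mirror_axis] %% 2L != 0L) {
    stop("extent along the mirror axis must be even (no midline voxel); got ",
         shape[mirror_axis], " on axis ", mirror_axis)
  }
  if (mask_kind == "box") {
    mask <- array(TRUE, dim = shape)
  } else {
    # inscribed ellipsoid; centre sits between the two middle slabs so the
    # mask is exactly mirror-symmetric
    ctr <- (shape + 1) / 2
    semi <- shape / 2
    ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - ctr[a]) / semi[a])^2)
    d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
    mask <- d2 <= 1
  }
  g <- structure(
    list(shape = shape, mirror_axis = as.integer(mirror_axis),
         mask = mask, voxel_size_mm = voxel_size_mm),
    class = "lat_grid"
  )
  stopifnot(identical(g$mask, mirror_volume(g$mask, g)))
  g
}

#' @export
print.lat_grid <- function(x, ...) {
  cat("<lat_grid> ", paste(x$shape, collapse = "x"),
      " voxels (", x$voxel_size_mm, " mm), mirror axis ", x$mirror_axis,
      ", ", sum(x$mask), " in-mask voxels (", sum(half_mask(x)),
      " homologous pairs)\n", sep = "")
  invisible(x)
}

#' Flip a volume across the grid's mirror axis
#'
#' @param volume 3-D array matching `grid$shape`.
#' @param grid a [make_symmetric_grid()] object.
#' @return the mirrored array.
#' @export
mirror_volume <- function(volume, grid) {
  stopifnot(all(dim(volume) == grid$shape))
  idx <- lapply(1:3, function(a) {
    if (a == grid$mirror_axis) rev(seq_len(grid$shape[a])) else seq_len(grid$shape[a])
  })
  do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
}

#' Half-grid mask of homologous voxel pairs
#'
#' @param grid a [make_symmetric_grid()] object.
#' @return logical array over the half grid (mirror axis extent halved),
#'   indexed by distance from the midline.
#' @export
half_mask <- function(grid) {
  extract_half(grid$mask, grid, "right")
}

# pull one hemisphere out of a full volume, re-indexed by distance from the
# midline so homologous pairs share indices
extract_half <- function(volume, grid, side = c("left", "right")) {
  side <- match.arg(side)
  a <- grid$mirror_axis
  n <- grid$shape[a]
  idx <- lapply(1:3, function(ax) seq_len(grid$shape[ax]))
  idx[[a]] <- if (side == "right") (n / 2 + 1):n else (n / 2):1
  do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
}

# inverse of extract_half for both halves at once
assemble_full <- function(left_half, right_half, grid) {
  a <- grid$mirror_axis
  n <- grid$shape[a]
  out <- array(0, dim = grid$shape)
  idx <- lapply(1:3, function(ax) seq_len(grid$shape[ax]))
  idx_l <- idx; idx_l[[a]] <- (n / 2):1
  idx_r <- idx; idx_r[[a]] <- (n / 2 + 1):n
  out <- do.call(`[<-`, c(list(out), idx_l, list(left_half)))
  out <- do.call(`[<-`, c(list(out), idx_r, list(right_half)))
  out
}

#' Split a volume into hemisphere halves
#'
#' Both halves are returned on the half grid, the left half already flipped
#' so that equal indices refer to homologous voxels. Reassembling the two
#' halves reconstructs the input exactly.
#'
#' @inheritParams mirror_volume
#' @return list with 3-D arrays `left` and `right`.
#' @export
split_hemispheres <- function(volume, grid) {
  if (!all(dim(volume) == grid$shape)) {
    stop("volume shape (", paste(dim(volume), collapse = "x"),
         ") does not match grid (", paste(grid$shape, collapse = "x"), ")")
  }
  list(left = extract_half(volume, grid, "left"),
       right = extract_half(volume, grid, "right"))
}

# linear indices (into half-grid arrays) of in-mask half voxels, fixed order
half_indices <- function(grid) which(half_mask(grid))

#' Distance of half-grid voxels to the interhemispheric plane
#'
#' Half-grid arrays are indexed by distance from the midline, so a voxel at
#' half index `h` along the mirror axis sits `(h - 0.5) * voxel_size_mm`
#' millimetres from the interhemispheric plane (identical in both
#' hemispheres by symmetry).
#'
#' @param grid a [make_symmetric_grid()] object.
#' @return numeric vector over in-mask half-grid voxels (order of
#'   `which(half_mask(grid))`).
#' @export
midline_distance_mm <- function(grid) {
  hm <- half_mask(grid)
  ijk <- which(hm, arr.ind = TRUE)
  (ijk[, grid$mirror_axis] - 0.5) * grid$voxel_size_mm
}
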