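#' @section Seeding:
#' All generators take a single integer seed. Internally a master seed is
#' expanded into per-stage child seeds with a counter scheme
#' (`child_seed(seed, k)`), so adding a stage never shifts the random stream
#' of another stage.
#' @keywords internal
#' @name latmorph-seeding
NULL

# deterministic counter-based child seeds, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1048573) * 2039 + k * 101 + 17L)
}

# smooth standardised random field on the half grid (white noise smoothed
# within the half mask, rescaled to unit sd over the mask)
smooth_field <- function(grid, fwhm_mm) {
  hm <- half_mask(grid)
  f <- array(stats::rnorm(length(hm)), dim = dim(hm))
  f <- smooth_gaussian(f, fwhm_mm, grid$voxel_size_mm, hm)
  v <- f[hm]
  f[hm] <- (v - mean(v)) / stats::sd(v)
  f
}

# multi-focus pattern on the half grid: a few signed Gaussian foci at random
# in-mask locations (a crude activation network), standardised to zero mean
# and unit sd over the mask (zero mean: a lateralisation pattern is a
# balanced push-pull contrast, and a nonzero spatial mean would survive
# voxel permutation and leak into permutation nulls)
blob_field <- function(grid, n_foci, focus_fwhm_mm) {
  hm <- half_mask(grid)
  ijk <- which(hm, arr.ind = TRUE)
  sigma <- focus_fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  f <- numeric(nrow(ijk))
  for (b in seq_len(n_foci)) {
    ctr <- ijk[sample.int(nrow(ijk), 1), ]
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.8, 1.2)
    f <- f + amp * exp(-rowSums(sweep(ijk, 2, ctr)^2) / (2 * sigma^2))
  }
  out <- array(0, dim = dim(hm))
  out[hm] <- (f - mean(f)) / stats::sd(f)
  out
}

#' Generate term maps with planted archetype lateralisation structure
#'
#' Builds a set of symmetric-grid volumes whose laterality-index (LI)
#' patterns are noisy convex mixtures of a small number of planted smooth
#' "archetype" patterns, the synthetic analogue of a meta-analytic term-map
#' database with a triangular (Pareto-like) lateralisation structure. Each
#' term volume is a shared symmetric background plus/minus half the LI
#' pattern in the right/left hemisphere, so right-half minus mirrored
#' left-half reproduces the planted LI exactly (before smoothing).
#'
#' Term families: roughly one in ten terms per archetype is a pure vertex
#' term (mixture weight 1), emulating families of closely related terms
#' that share a functional profile; the remaining weights come from a
#' sparse Dirichlet, so the cloud fills the simplex with mass near its
#' vertices. Archetype patterns are compact multi-focus activation networks
#' (signed Gaussian foci). The LI noise has two Gaussian parts: white
#' voxel noise of sd `noise_sd`, and a long tail of weak shared "minor
#' networks" with standard-normal term weights and amplitude
#' `minor_scale * noise_sd`, emulating the slowly decaying covariance
#' spectrum of real map collections (this is what gives the grand-average
#' retention rule a realistic component count; both parts vanish when
#' `noise_sd = 0`). The shared symmetric background is a sparse
#' non-negative mixture of a few bilateral focus networks, so the original
#' (un-differenced) maps carry consistent bilateral structure for the
#' non-lateralised analysis to find.
#'
#' @param grid a [make_symmetric_grid()] object.
#' @param n_terms number of term maps (>= 3 * n_archetypes).
#' @param n_archetypes 3 or 4 planted archetypes.
#' @param noise_sd sd of i.i.d. Gaussian noise added to each term's LI
#'   pattern (same activation units as the unit-sd archetype fields).
#' @param seed integer master seed.
#' @param background_sd amplitude (sd units) of the bilateral background
#'   networks.
#' @param background_offset constant added to all volumes so activations are
#'   positive (as in non-negative meta-analytic evidence maps).
#' @param n_background number of bilateral background networks.
#' @param n_foci Gaussian foci per pattern.
#' @param focus_fwhm_mm FWHM (mm) of each Gaussian focus.
#' @param n_minor number of weak shared noise networks.
#' @param minor_scale amplitude of each minor network relative to
#'   `noise_sd`.
#' @param dirichlet_alpha concentration of the mixture-weight Dirichlet;
#'   values < 1 push terms towards simplex vertices and edges.
#' @return list with `maps` (a `term_maps` object: `volumes` list, `terms`,
#'   `grid`) and `truth` (a `planted_truth` object: `archetype_patterns`
#'   K x voxel matrix over the half mask, `archetype_coords`, `term_weights`,
#'   plus the generator parameters).
#' @export
generate_term_maps <- function(grid, n_terms = 60, n_archetypes = 3,
                               noise_sd = 0.1, seed = 1,
                               background_sd = 2, background_offset = 5,
                               n_background = 3, n_foci = 3,
                               focus_fwhm_mm = 10, n_minor = 80,
                               minor_scale = 0.45, dirichlet_alpha = 0.2) {
  if (!n_archetypes %in% c(3L, 4L)) stop("'n_archetypes' must be 3 or 4")
  if (n_terms < 3 * n_archetypes) stop("'n_terms' must be >= 3 * n_archetypes")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  hm <- half_mask(grid)
  hi <- which(hm)
  nv <- length(hi)

  set.seed(child_seed(seed, 1L))
  A <- t(vapply(seq_len(n_archetypes),
                function(k) blob_field(grid, n_foci, focus_fwhm_mm)[hi],
                numeric(nv)))
  # archetypes are maximally distinct specialised profiles: orthogonalise
  # the raw focus networks (Gram-Schmidt), keep orientation and unit sd
  A0 <- A
  A <- t(qr.Q(qr(t(A))))
  A <- A / apply(A, 1, stats::sd) * sign(rowSums(A * A0))
  B <- t(vapply(seq_len(n_background),
                function(k) blob_field(grid, n_foci, focus_fwhm_mm)[hi],
                numeric(nv)))

  set.seed(child_seed(seed, 2L))
  W <- matrix(stats::rgamma(n_terms * n_archetypes, shape = dirichlet_alpha),
              n_terms, n_archetypes)
  W <- W / rowSums(W)
  # term families: pure vertex terms, roughly one in ten per archetype
  n_pure <- max(1L, n_terms %/% 10L)
  pure <- rep(seq_len(n_archetypes), each = n_pure)
  for (i in seq_along(pure)) {
    W[i, ] <- 0
    W[i, pure[i]] <- 1
  }
  # background loadings are standard normal: every term engages (up- or
  # down-regulates) each bilateral network, giving the original maps a
  # consistent bilateral covariance structure in both hemispheres
  V <- matrix(stats::rnorm(n_terms * n_background), n_terms, n_background)

  set.seed(child_seed(seed, 3L))
  li <- W %*% A
  if (noise_sd > 0) {
    li <- li + matrix(stats::rnorm(length(li), sd = noise_sd),
                      nrow = n_terms)
    if (n_minor > 0) {
      Mn <- t(vapply(seq_len(n_minor),
                     function(k) blob_field(grid, n_foci, focus_fwhm_mm)[hi],
                     numeric(nv)))
      li <- li + (minor_scale * noise_sd) *
        (matrix(stats::rnorm(n_terms * n_minor), n_terms) %*% Mn)
    }
  }
  bgm <- background_offset + background_sd * (V %*% B)

  terms <- sprintf("term%03d", seq_len(n_terms))
  volumes <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    bg <- array(0, dim = dim(hm)); bg[hi] <- bgm[t, ]
    li_half <- array(0, dim = dim(hm)); li_half[hi] <- li[t, ]
    left <- (bg - li_half / 2) * hm
    right <- (bg + li_half / 2) * hm
    volumes[[t]] <- assemble_full(left, right, grid)
  }
  coords <- switch(as.character(n_archetypes),
                   "3" = rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)),
                   "4" = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  maps <- structure(list(volumes = volumes, terms = terms, grid = grid),
                    class = "term_maps")
  truth <- structure(
    list(archetype_patterns = A, archetype_coords = coords, term_weights = W,
         background_patterns = B, background_weights = V,
         noise_sd = noise_sd, background_sd = background_sd,
         background_offset = background_offset,
         focus_fwhm_mm = focus_fwhm_mm, seed = seed),
    class = "planted_truth")
  list(maps = maps, truth = truth)
}

#' Generate exchangeable-hemisphere null maps
#'
#' Volumes whose left and right hemisphere values are identically
#' distributed (a shared symmetric background plus independent noise in each
#' hemisphere), so any apparent lateralisation is chance. Used to calibrate
#' the family-wise error of the significance test.
#'
#' @inheritParams generate_term_maps
#' @param noise_sd sd of the independent per-hemisphere Gaussian noise.
#' @return a `term_maps` object.
#' @export
generate_null_maps <- function(grid, n_terms = 40, noise_sd = 1, seed = 1,
                               background_sd = 2, background_offset = 5,
                               pattern_fwhm_mm = 6) {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  hm <- half_mask(grid)
  set.seed(child_seed(seed, 11L))
  terms <- sprintf("null%03d", seq_len(n_terms))
  volumes <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    bg <- background_offset + background_sd * smooth_field(grid, pattern_fwhm_mm)
    left <- (bg + array(stats::rnorm(length(hm), sd = noise_sd), dim(hm))) * hm
    right <- (bg + array(stats::rnorm(length(hm), sd = noise_sd), dim(hm))) * hm
    volumes[[t]] <- assemble_full(left, right, grid)
  }
  structure(list(volumes = volumes, terms = terms, grid = grid),
            class = "term_maps")
}

#' Generate per-subject callosal connectivity with planted dominance link
#'
#' Emulates the inputs of the connectivity analysis: for every half-grid
#' voxel, a per-subject binary indicator of a connection to the corpus
#' callosum (Bernoulli with probability linear in the absolute planted
#' dominance), and a per-subject axonal-water-fraction value for the
#' callosal voxel that the cortical voxel projects to (one callosal locus
#' per cortical voxel), whose mean is shifted by `awf_offset` for voxels
#' flagged as lateralised.
#'
#' @param grid a [make_symmetric_grid()] object.
#' @param dominance numeric vector over half-mask voxels, radians in
#'   \[-pi/4, pi/4\] (0 for non-lateralised voxels).
#' @param conn_slope linear coefficient of connection probability on
#'   `abs(dominance)`; negative plants the reduced-connectivity effect.
#' @param awf_offset additive shift of mean axonal water fraction for
#'   lateralised-projecting callosal voxels (negative = lower).
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer master seed.
#' @param p_base connection probability at zero dominance.
#' @param awf_base mean axonal water fraction of non-lateralised
#'   projections (fraction in \[0, 1\]).
#' @param awf_sd sd of per-subject, per-voxel axonal water fraction.
#' @param lateralised logical vector flagging lateralised voxels; defaults
#'   to `dominance != 0`.
#' @return object of class `subject_connectivity`: list with `indicator`
#'   (subjects x voxels binary matrix), `awf` (subjects x callosal-voxels),
#'   `p_true`, `n_subjects`, `lateralised`, `grid`.
#' @export
generate_connectivity <- function(grid, dominance, conn_slope = -3.2,
                                  awf_offset = -0.05, n_subjects = 163,
                                  seed = 1, p_base = 0.6, awf_base = 0.35,
                                  awf_sd = 0.05,
                                  lateralised = dominance != 0) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  nv <- length(dominance)
  p_raw <- p_base + conn_slope * abs(dominance)
  if (any(p_raw < 0 | p_raw > 1)) {
    warning("planted connection probabilities outside [0, 1] before clipping (",
            sum(p_raw < 0 | p_raw > 1), " voxels)")
  }
  p <- pmin(1, pmax(1 / n_subjects, p_raw))
  set.seed(child_seed(seed, 21L))
  ind <- matrix(stats::rbinom(n_subjects * nv, 1L, rep(p, each = n_subjects)),
                nrow = n_subjects)
  set.seed(child_seed(seed, 22L))
  mu <- awf_base + awf_offset * as.numeric(lateralised)
  awf <- matrix(stats::rnorm(n_subjects * nv, mean = rep(mu, each = n_subjects),
                             sd = awf_sd), nrow = n_subjects)
  awf <- pmin(pmax(awf, 0), 1)   # argument order keeps the dim attribute
  structure(list(indicator = ind, awf = awf, p_true = p,
                 n_subjects = as.integer(n_subjects),
                 lateralised = lateralised, grid = grid),
            class = "subject_connectivity")
}

#' Planted archetype LI patterns at the analysis smoothing scale
#'
#' Recovery tests compare reconstructed archetype maps against the planted
#' patterns after the same Gaussian smoothing that the analysis applies to
#' the data, i.e. against the planted truth as it appears on the analysis
#' scale.
#'
#' @param truth a `planted_truth` object.
#' @param grid the grid the truth was generated on.
#' @param fwhm_mm analysis smoothing FWHM in mm.
#' @return K x voxel matrix over the half mask.
#' @export
planted_archetype_li <- function(truth, grid, fwhm_mm) {
  hm <- half_mask(grid)
  hi <- which(hm)
  t(apply(truth$archetype_patterns, 1, function(a) {
    f <- array(0, dim(hm)); f[hi] <- a
    smooth_gaussian(f, fwhm_mm, grid$voxel_size_mm, hm)[hi]
  }))
}
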