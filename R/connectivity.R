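#' Non-lateralised but functionally involved voxels
#'
#' Reruns the component-significance machinery per hemisphere on the
#' original (un-differenced) smoothed hemisphere maps and returns, on the
#' half grid, the voxels that (1) pass the significance threshold for at
#' least one component in at least one hemisphere, (2) do not overlap the
#' lateralised voxels, and (3) whose homologue in the opposite hemisphere
#' also meets (1) and (2). Because lateralisation is a property of
#' homologous pairs, the result reduces to: significant in both
#' hemispheres' analyses and not lateralised.
#'
#' @param halves list with smoothed `left`/`right` matrices and `grid`, as
#'   from [hemisphere_matrices()].
#' @param lateralised_mask logical vector over half-mask voxels (the `any`
#'   field of a [permutation_significance()] result).
#' @param n_perm,alpha,cluster_min,connectivity,seed passed to
#'   [permutation_significance()] for each hemisphere's analysis.
#' @return list with `nonlateralised` (logical over half-mask voxels),
#'   `sig_left`, `sig_right` (per-hemisphere significance), and the two
#'   hemisphere `significance_mask` objects.
#' @export
nonlateralised_mask <- function(halves, lateralised_mask, n_perm = 1000,
                                alpha = 0.05, cluster_min = 20,
                                connectivity = 26, seed = 1) {
  grid <- halves$grid
  run_hemi <- function(X, s) {
    Xc <- X
    attr(Xc, "grid") <- grid
    m <- rotate_model(fit_pca(Xc))
    permutation_significance(Xc, m, n_perm = n_perm, alpha = alpha,
                             cluster_min = cluster_min,
                             connectivity = connectivity, seed = s,
                             grid = grid)
  }
  sl <- run_hemi(halves$left, child_seed(seed, 31L))
  sr <- run_hemi(halves$right, child_seed(seed, 32L))
  nonlat <- sl$any & sr$any & !lateralised_mask
  if (!any(nonlat)) {
    stop("no non-lateralised voxels satisfy the three criteria; ",
         "the connectivity contrast cannot proceed")
  }
  list(nonlateralised = nonlat, sig_left = sl$any, sig_right = sr$any,
       mask_left = sl, mask_right = sr)
}

#' Per-voxel probability of connection
#'
#' Fraction of subjects in which a voxel connects (by at least one
#' streamline) to the corpus callosum: the per-voxel mean of the binary
#' subject indicators.
#'
#' @param sc a `subject_connectivity` object (or any subjects x voxels
#'   binary matrix).
#' @return numeric vector of per-voxel fractions, multiples of
#'   1/n_subjects.
#' @export
probability_of_connection <- function(sc) {
  ind <- if (inherits(sc, "subject_connectivity")) sc$indicator else as.matrix(sc)
  if (!all(ind %in% c(0, 1))) stop("indicator matrix must be binary")
  colMeans(ind)
}

#' Sampled difference distributions of connectivity between pools
#'
#' Repeatedly samples a fixed fraction of voxels (without replacement) from
#' the lateralised and the non-lateralised pool, and records, per
#' repetition, the difference (lateralised minus non-lateralised) in mean
#' probability of connection and in the replicability-weighted mean callosal
#' axonal water fraction. A callosal voxel's weight is the fraction of
#' subjects in which it connects to at least one voxel of the sampled
#' subset; with one callosal locus per cortical voxel this is the sampled
#' voxel's own connection probability.
#'
#' @param pools list with integer vectors `lat` and `nonlat` indexing
#'   half-mask voxels (both non-empty).
#' @param sc a `subject_connectivity` object.
#' @param frac sampled fraction of each pool (default 0.05).
#' @param n_rep repetitions (default 1000).
#' @param seed integer seed.
#' @return list with numeric vectors `diff_p_conn` and `diff_awf` of length
#'   `n_rep`.
#' @export
sample_difference_distribution <- function(pools, sc, frac = 0.05,
                                           n_rep = 1000, seed = 1) {
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  if (!length(pools$lat) || !length(pools$nonlat)) {
    stop("both pools must be non-empty")
  }
  p_conn <- probability_of_connection(sc)
  awf_bar <- colMeans(sc$awf)
  n_lat <- ceiling(frac * length(pools$lat))
  n_non <- ceiling(frac * length(pools$nonlat))
  if (n_lat < 1 || n_non < 1) stop("sample size of zero voxels")
  set.seed(seed)
  dp <- da <- numeric(n_rep)
  n_undefined <- 0L
  for (r in seq_len(n_rep)) {
    s1 <- pools$lat[sample.int(length(pools$lat), n_lat)]
    s2 <- pools$nonlat[sample.int(length(pools$nonlat), n_non)]
    dp[r] <- mean(p_conn[s1]) - mean(p_conn[s2])
    w1 <- p_conn[s1]; w2 <- p_conn[s2]
    if (sum(w1) == 0 || sum(w2) == 0) {
      # no observed connection in a sampled subset: the replicability-
      # weighted mean is undefined for this repetition
      da[r] <- NA_real_
      n_undefined <- n_undefined + 1L
    } else {
      da[r] <- sum(w1 * awf_bar[s1]) / sum(w1) - sum(w2 * awf_bar[s2]) / sum(w2)
    }
  }
  if (n_undefined > 0) {
    message(n_undefined, " of ", n_rep, " repetitions had no connected ",
            "voxel in a sample; their weighted awf difference is NA")
  }
  list(diff_p_conn = dp, diff_awf = da)
}

#' Hemispheric dominance in radians
#'
#' `atan(right / left) - pi/4`, computed as `atan2(right, left) - pi/4` for
#' non-negative activation strengths: 0 for balanced activity, +pi/4 for
#' purely right-hemisphere activity, -pi/4 for purely left. Voxels with
#' both strengths zero are undefined and returned as `NA`.
#'
#' @param left_act,right_act non-negative activation strengths
#'   (vectorised).
#' @return dominance in radians, in \[-pi/4, pi/4\].
#' @export
dominance <- function(left_act, right_act) {
  if (any(left_act < 0 | right_act < 0, na.rm = TRUE)) {
    stop("activation strengths must be non-negative")
  }
  d <- atan2(right_act, left_act) - pi / 4
  both0 <- left_act == 0 & right_act == 0
  if (any(both0)) {
    message(sum(both0), " voxel(s) with zero activity in both hemispheres ",
            "excluded from dominance")
    d[both0] <- NA_real_
  }
  d
}

#' Component activation strengths per hemisphere
#'
#' The activation strength of a component in one hemisphere at a voxel is
#' the loading-weighted mean of that hemisphere's activation values across
#' terms, using the component's positive loadings as weights (terms that
#' express the component). Activations are non-negative by construction of
#' meta-analytic evidence maps, so the strengths are non-negative inputs
#' for [dominance()].
#'
#' @param left,right terms x voxels matrices of hemisphere activations
#'   (e.g. the smoothed halves from [hemisphere_matrices()]).
#' @param loadings term x component rotated loading matrix.
#' @return list with component x voxel matrices `left` and `right`.
#' @export
component_hemisphere_strengths <- function(left, right, loadings) {
  W <- pmax(as.matrix(loadings), 0)
  deg <- colSums(W)
  if (any(deg == 0)) {
    # a component with no positive loading: fall back to absolute weights
    W[, deg == 0] <- abs(loadings[, deg == 0, drop = FALSE])
    deg <- colSums(W)
  }
  W <- sweep(W, 2, deg, `/`)
  list(left = pmax(crossprod(W, as.matrix(left)), 0),
       right = pmax(crossprod(W, as.matrix(right)), 0))
}

#' Assign per-voxel dominance from the strongest component
#'
#' Where lateralised regions of several components overlap, each voxel
#' takes the dominance of the component with the largest absolute GLM
#' z-score there (ties resolved to the lowest component index). Dominance
#' is computed from that component's left- and right-hemisphere activation
#' strengths at the voxel.
#'
#' @param z component x voxel z-score matrix.
#' @param left_strength,right_strength component x voxel non-negative
#'   activation strengths.
#' @param voxel_mask logical vector: voxels covered by at least one
#'   significant component (dominance defined only there).
#' @return list with `dominance` (voxel vector, `NA` off-mask),
#'   `component_id` (argmax component per voxel, `NA` off-mask).
#' @export
assign_voxel_dominance <- function(z, left_strength, right_strength,
                                   voxel_mask = rep(TRUE, ncol(z))) {
  nv <- ncol(z)
  cid <- apply(abs(z), 2, which.max)   # which.max takes the first on ties
  cid[!voxel_mask] <- NA_integer_
  dom <- rep(NA_real_, nv)
  on <- which(voxel_mask)
  idx <- cbind(cid[on], on)
  dom[on] <- dominance(left_strength[idx], right_strength[idx])
  list(dominance = dom, component_id = cid)
}

#' Logarithmically spaced connection-probability bins
#'
#' Bin edges increase geometrically with ratio 2, anchored so the first
#' (smallest) bin width equals the measurement resolution `1/n_subjects`;
#' the top edge is capped at 1. Bin widths therefore double from bin to bin
#' (the capped top bin may be narrower), compensating for connection
#' probabilities piling up at small values.
#'
#' @param p_conn_values probabilities in \[0, 1\].
#' @param n_subjects number of subjects (>= 2) setting the resolution.
#' @return list with `bin` (integer assignment per value, `NA` for empty
#'   input), `edges` (increasing, first edge `1/n_subjects`), `n_bins`.
#'   Empty bins are dropped and assignments renumbered.
#' @export
bin_by_probability <- function(p_conn_values, n_subjects) {
  if (n_subjects < 2) stop("'n_subjects' must be >= 2")
  if (any(p_conn_values < 0 | p_conn_values > 1, na.rm = TRUE)) {
    stop("probabilities must be in [0, 1]")
  }
  lo <- 1 / n_subjects
  n_up <- ceiling(log2(n_subjects))
  edges <- lo * 2^(0:n_up)
  edges[length(edges)] <- 1
  # values live in [1/n, 1]; first bin is [lo, 2*lo], width exactly 1/n
  bin <- findInterval(p_conn_values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keep <- sort(unique(bin[!is.na(bin)]))
  list(bin = match(bin, keep), edges = edges, n_bins = length(keep))
}

#' Correlation between binned dominance and connection probability
#'
#' Bins voxels by connection probability ([bin_by_probability()]), then
#' correlates the bin means of absolute dominance with the bin means of
#' connection probability (Pearson). With a covariate (mean bilateral
#' activity), both binned variables are residualised on the binned
#' covariate first, giving a partial correlation.
#'
#' @param dom voxel dominance in radians (`NA` allowed, dropped).
#' @param p_conn voxel connection probabilities.
#' @param n_subjects subject count defining the bin resolution.
#' @param covariate optional per-voxel covariate of non-interest.
#' @return list with `r`, `n_bins`, `bin_means` (data frame).
#' @export
dominance_connectivity_correlation <- function(dom, p_conn, n_subjects,
                                               covariate = NULL) {
  ok <- !is.na(dom) & !is.na(p_conn)
  dom <- dom[ok]; p_conn <- p_conn[ok]
  if (!is.null(covariate)) covariate <- covariate[ok]
  b <- bin_by_probability(p_conn, n_subjects)
  if (b$n_bins < 3) stop("need at least 3 populated probability bins, got ",
                         b$n_bins)
  mdom <- tapply(abs(dom), b$bin, mean)
  mp <- tapply(p_conn, b$bin, mean)
  if (is.null(covariate)) {
    r <- stats::cor(mdom, mp)
  } else {
    mc <- tapply(covariate, b$bin, mean)
    rd <- stats::resid(stats::lm(mdom ~ mc))
    rp <- stats::resid(stats::lm(mp ~ mc))
    r <- stats::cor(rd, rp)
  }
  list(r = unname(r), n_bins = b$n_bins,
       bin_means = data.frame(p_conn = as.numeric(mp),
                              abs_dominance = as.numeric(mdom)))
}

#' Distance control for the pool connectivity contrast
#'
#' Tests whether the lateralised-minus-non-lateralised connectivity
#' difference depends on distance from the interhemispheric midline. Each
#' lateralised voxel is matched to the non-lateralised voxel closest in
#' midline distance; the per-pair difference in connection probability is
#' then correlated with the lateralised voxel's distance.
#'
#' @param pools list with `lat` and `nonlat` half-mask voxel indices.
#' @param p_conn per-voxel connection probabilities.
#' @param dist_mm per-voxel distance to the midline plane (e.g.
#'   [midline_distance_mm()] subset to the half mask order used by
#'   `p_conn`).
#' @return list with `r` (Pearson correlation of difference vs distance)
#'   and `pairs` (data frame).
#' @export
distance_control <- function(pools, p_conn, dist_mm) {
  dl <- dist_mm[pools$lat]
  dn <- dist_mm[pools$nonlat]
  if (stats::sd(dl) == 0) stop("all lateralised voxels are equidistant ",
                               "from the midline; correlation undefined")
  match_idx <- vapply(dl, function(d) which.min(abs(dn - d)), integer(1))
  diff <- p_conn[pools$lat] - p_conn[pools$nonlat][match_idx]
  r <- stats::cor(diff, dl)
  list(r = unname(r),
       pairs = data.frame(dist_mm = dl, diff_p_conn = diff))
}
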