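test_that("dominance closed forms and antisymmetry", {
  expect_equal(dominance(1, 1), 0)
  expect_equal(dominance(0, 1), pi / 4)
  expect_equal(dominance(1, 0), -pi / 4)
  set.seed(23)
  l <- runif(50); r <- runif(50)
  expect_equal(dominance(l, r), -dominance(r, l), tolerance = 1e-12)
  expect_true(all(abs(dominance(l, r)) <= pi / 4 + 1e-12))
  expect_message(d0 <- dominance(c(0, 1), c(0, 1)), "zero activity")
  expect_true(is.na(d0[1]) && d0[2] == 0)
  expect_error(dominance(-1, 1), "non-negative")
})

test_that("voxel dominance comes from the largest-|z| component", {
  z <- rbind(c(3.1, 1, 0.5), c(-2.2, 1, 0.5))
  ls <- rbind(c(1, 1, 2), c(1, 2, 0))
  rs <- rbind(c(1, 0, 2), c(0, 2, 4))
  out <- assign_voxel_dominance(z, ls, rs, voxel_mask = c(TRUE, TRUE, FALSE))
  expect_equal(out$component_id[1:2], c(1, 1))   # |3.1| > |-2.2|; tie -> first
  expect_equal(out$dominance[1], dominance(1, 1))
  expect_true(is.na(out$dominance[3]))
  # tie in |z| resolves to the lowest component index
  zt <- rbind(c(2, 2), c(2, 2))
  expect_equal(assign_voxel_dominance(zt, ls[, 1:2], rs[, 1:2])$component_id,
               c(1, 1))
})

test_that("probability of connection is the subject mean", {
  ind <- rbind(rep(1, 4), rep(1, 4), rep(0, 4))
  expect_equal(probability_of_connection(ind), rep(2 / 3, 4))
  expect_equal(probability_of_connection(matrix(1, 5, 2)), c(1, 1))
  expect_equal(probability_of_connection(matrix(0, 5, 2)), c(0, 0))
  ind163 <- matrix(rep(c(rep(1, 81), rep(0, 82)), 2), ncol = 2)
  expect_equal(probability_of_connection(ind163), rep(81 / 163, 2))
  expect_error(probability_of_connection(matrix(2, 3, 3)), "binary")
})

test_that("probability bins are geometric with resolution-width first bin", {
  b <- bin_by_probability(seq(1 / 163, 1, length.out = 400), 163)
  w <- diff(b$edges)
  expect_equal(w[1], 1 / 163)
  expect_equal(b$edges[1], 1 / 163)
  expect_equal(b$edges[length(b$edges)], 1)
  # widths double except for the final capped bin
  expect_true(all(diff(w[-length(w)]) > 0))

  # power-of-two subject count: strictly increasing widths throughout
  b2 <- bin_by_probability(seq(1 / 128, 1, length.out = 100), 128)
  expect_true(all(diff(diff(b2$edges)) > 0) || all(diff(b2$edges) > 0))
  expect_true(!is.unsorted(diff(b2$edges), strictly = TRUE))

  # all values in one bin
  b3 <- bin_by_probability(rep(0.9, 10), 16)
  expect_equal(b3$n_bins, 1)
  expect_error(bin_by_probability(0.5, 1), ">= 2")
  expect_error(bin_by_probability(c(0.5, 1.2), 10), "0, 1")
})

test_that("binned dominance-connectivity correlation behaves", {
  n <- 163
  # perfect linear negative relation -> r = -1
  p <- seq(1 / n, 1, length.out = 500)
  dom <- pi / 4 * (1 - p)
  r <- dominance_connectivity_correlation(dom, p, n)
  expect_equal(r$r, -1, tolerance = 1e-10)
  expect_gte(r$n_bins, 3)

  # independent dominance -> weak correlation
  set.seed(24)
  r0 <- dominance_connectivity_correlation(runif(2000, 0, pi / 4),
                                           sample(p, 2000, TRUE), n)
  expect_lt(abs(r0$r), 0.5)

  # an association driven purely by a shared covariate is removed by the
  # partial correlation
  set.seed(25)
  cov <- runif(4000)
  p2 <- pmin(1, pmax(1 / n, round(n * (0.2 + 0.6 * cov + rnorm(4000, sd = 0.03))) / n))
  dom2 <- pi / 4 * pmin(1, pmax(0, 0.7 * cov + runif(4000, 0, 0.3)))
  raw <- dominance_connectivity_correlation(dom2, p2, n)
  prt <- dominance_connectivity_correlation(dom2, p2, n, covariate = cov)
  expect_gt(raw$r, 0.8)
  expect_lt(abs(prt$r), 0.6)

  expect_error(dominance_connectivity_correlation(rep(0.1, 5), rep(0.5, 5), 163),
               "3 populated")
})

test_that("pool difference distributions centre on the planted effects", {
  g <- make_symmetric_grid(c(12, 12, 12), "box")
  nv <- sum(half_mask(g))
  set.seed(26)
  dom <- numeric(nv)
  lat <- sample(nv, floor(nv / 3))
  dom[lat] <- runif(length(lat), 0.1, pi / 4) * sample(c(-1, 1), length(lat), TRUE)
  pools <- list(lat = lat, nonlat = setdiff(seq_len(nv), lat))

  # identical pools: both distributions centred at zero
  sc0 <- generate_connectivity(g, dom, conn_slope = 0, awf_offset = 0,
                               n_subjects = 80, seed = 3, p_base = 0.5)
  same <- list(lat = lat, nonlat = lat)
  d0 <- sample_difference_distribution(same, sc0, frac = 0.2, n_rep = 300,
                                       seed = 4)
  expect_lt(abs(mean(d0$diff_p_conn)), 2 * sd(d0$diff_p_conn) / sqrt(300) + 1e-3)
  expect_lt(abs(mean(d0$diff_awf, na.rm = TRUE)), 0.003)

  # planted awf offset appears in the weighted difference
  sc1 <- generate_connectivity(g, dom, conn_slope = 0, awf_offset = -0.05,
                               n_subjects = 80, seed = 5, p_base = 0.5,
                               lateralised = seq_len(nv) %in% lat)
  d1 <- sample_difference_distribution(pools, sc1, frac = 0.1, n_rep = 500,
                                       seed = 6)
  expect_lt(abs(mean(d1$diff_awf, na.rm = TRUE) + 0.05), 0.01)

  expect_error(sample_difference_distribution(list(lat = integer(0),
                                                   nonlat = 1:5), sc1),
               "non-empty")
  expect_error(sample_difference_distribution(pools, sc1, frac = 0), "frac")
})

test_that("distance control distinguishes planted distance effects", {
  g <- make_symmetric_grid(c(12, 12, 12), "box")
  nv <- sum(half_mask(g))
  dist <- midline_distance_mm(g)
  set.seed(27)
  lat <- sample(nv, 200)
  pools <- list(lat = lat, nonlat = setdiff(seq_len(nv), lat))

  # distance-independent connectivity -> |r| near 0
  p0 <- rep(0.5, nv) + rnorm(nv, sd = 0.05)
  r0 <- distance_control(pools, p0, dist)
  expect_lt(abs(r0$r), 0.2)

  # effect proportional to distance -> positive correlation
  p1 <- 0.3 + 0.04 * dist * (seq_len(nv) %in% lat) + rnorm(nv, sd = 0.02)
  r1 <- distance_control(pools, p1, dist)
  expect_gt(r1$r, 0.5)

  # all lateralised voxels equidistant -> rejected
  eq <- which(abs(dist - dist[1]) < 1e-9)[1:10]
  expect_error(distance_control(list(lat = eq, nonlat = pools$nonlat),
                                p0, dist), "equidistant")
})

test_that("non-lateralised voxels satisfy all three criteria", {
  ps <- planted_set()
  sig <- permutation_significance(ps$li, rotate_model(fit_pca(ps$li)),
                                  n_perm = 300, seed = 31, grid = ps$grid)
  nl <- nonlateralised_mask(ps$halves, sig$any, n_perm = 300, seed = 32)
  expect_true(any(nl$nonlateralised))
  # criterion 2: disjoint from lateralised voxels
  expect_equal(sum(nl$nonlateralised & sig$any), 0)
  # criteria 1 and 3: significant in both hemispheres' analyses
  expect_true(all(nl$sig_left[nl$nonlateralised]))
  expect_true(all(nl$sig_right[nl$nonlateralised]))
  # a voxel significant in one hemisphere only is excluded
  one_sided <- nl$sig_left & !nl$sig_right
  expect_equal(sum(nl$nonlateralised & one_sided), 0)
})
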