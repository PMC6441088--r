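test_that("noise-free term maps reproduce the planted convex mixtures", {
  g <- tiny_grid(c(10, 10, 10))
  gen <- generate_term_maps(g, n_terms = 12, n_archetypes = 3,
                            noise_sd = 0, seed = 4)
  li <- li_matrix(gen$maps, fwhm_mm = 0)
  planted <- gen$truth$term_weights %*% gen$truth$archetype_patterns
  expect_lt(max(abs(li - planted)), 1e-12)

  # convexity: unconstrained least squares on the archetypes recovers the
  # weights exactly (zero residual, non-negative, rows summing to one)
  A <- gen$truth$archetype_patterns
  W_hat <- t(qr.coef(qr(t(A)), t(li)))
  expect_equal(unname(W_hat), unname(gen$truth$term_weights), tolerance = 1e-8)
  expect_true(all(W_hat > -1e-10))
  expect_equal(unname(rowSums(W_hat)), rep(1, 12), tolerance = 1e-8)
})

test_that("generators are deterministic in the seed", {
  g <- tiny_grid()
  a <- generate_term_maps(g, 12, 3, 0.2, seed = 9)
  b <- generate_term_maps(g, 12, 3, 0.2, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a$maps$volumes[[1]],
    generate_term_maps(g, 12, 3, 0.2, seed = 10)$maps$volumes[[1]]))

  n1 <- generate_null_maps(g, 8, 1, seed = 3)
  expect_identical(n1, generate_null_maps(g, 8, 1, seed = 3))

  set.seed(77); dom <- runif(sum(half_mask(g)), -pi / 4, pi / 4)
  c1 <- suppressWarnings(generate_connectivity(g, dom, n_subjects = 20, seed = 5))
  c2 <- suppressWarnings(generate_connectivity(g, dom, n_subjects = 20, seed = 5))
  expect_identical(c1, c2)
})

test_that("generator preconditions are enforced", {
  g <- tiny_grid()
  expect_error(generate_term_maps(g, 12, 5, 0.1, seed = 1), "3 or 4")
  expect_error(generate_term_maps(g, 5, 3, 0.1, seed = 1), ">= 3")
  expect_error(generate_term_maps(g, 12, 3, -0.1, seed = 1), "non-negative")
  expect_error(generate_null_maps(g, 8, -1, seed = 1), "non-negative")
  expect_error(generate_connectivity(g, 0, n_subjects = 1, seed = 1), ">= 2")
})

test_that("null maps have exchangeable hemispheres", {
  g <- tiny_grid(c(8, 8, 8), "box")
  # mean LI across many independent maps is centred on zero
  li_all <- do.call(rbind, lapply(1:6, function(s) {
    li_matrix(generate_null_maps(g, 20, 1, seed = 100 + s), fwhm_mm = 0)
  }))
  expect_lt(abs(mean(li_all)), 3 * sd(li_all) / sqrt(length(li_all) / 10))
  # mirroring a null volume negates its LI values voxelwise
  maps <- generate_null_maps(g, 4, 1, seed = 5)
  li <- compute_li(maps$volumes[[1]], g, 6)$values
  li_m <- compute_li(mirror_volume(maps$volumes[[1]], g), g, 6)$values
  expect_equal(li_m, -li, tolerance = 1e-12)
})

test_that("connection indicators follow the planted dominance model", {
  g <- make_symmetric_grid(c(12, 12, 12), "box")
  nv <- sum(half_mask(g))
  set.seed(8)
  dom <- runif(nv, -pi / 4, pi / 4)

  # null: no slope, no offset
  sc0 <- generate_connectivity(g, dom, conn_slope = 0, awf_offset = 0,
                               n_subjects = 50, seed = 2, p_base = 0.5)
  p0 <- probability_of_connection(sc0)
  expect_lt(abs(cor(abs(dom), p0)), 0.1)
  expect_true(all(sc0$indicator %in% c(0, 1)))
  expect_true(all(sc0$awf >= 0 & sc0$awf <= 1))

  # negative slope -> negative dominance-probability correlation
  sc1 <- generate_connectivity(g, dom, conn_slope = -0.6, n_subjects = 163,
                               seed = 2, p_base = 0.8)
  p1 <- probability_of_connection(sc1)
  expect_lt(cor(abs(dom), p1), -0.5)
  # probabilities are multiples of 1/163
  expect_equal(p1 * 163, round(p1 * 163), tolerance = 1e-12)

  # probabilities leaving [0, 1] before clipping raise a warning
  expect_warning(
    generate_connectivity(g, dom, conn_slope = -3.2, n_subjects = 50,
                          seed = 2, p_base = 0.6),
    "clipping")
})
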