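# small shared fixtures, built in code at test time

tiny_grid <- function(shape = c(8, 8, 8), kind = "ellipsoid") {
  make_symmetric_grid(shape, kind)
}

# a quick planted term set on a 12^3 ellipsoid grid, cached per session
planted_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- make_symmetric_grid(c(12, 12, 12), "ellipsoid")
      gen <- generate_term_maps(grid, n_terms = 60, n_archetypes = 3,
                                noise_sd = 0.1, seed = 11)
      halves <- hemisphere_matrices(gen$maps, fwhm_mm = 6)
      li <- halves$right - halves$left
      attr(li, "grid") <- grid
      rownames(li) <- gen$maps$terms
      cache <<- list(grid = grid, gen = gen, halves = halves, li = li)
    }
    cache
  }
})

# random point cloud whose convex hull has at most max_hull vertices
random_hull_points <- function(n, seed, max_hull = 8) {
  set.seed(seed)
  repeat {
    P <- matrix(rnorm(2 * n), ncol = 2)
    if (length(grDevices::chull(P)) <= max_hull) return(P)
  }
}
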