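# Brute-force oracle for the minimal enclosing triangle, independent of the
# package's search: for every hull edge taken as the flush side, the areas
# of all support-line triangles are evaluated on a dense angle grid that is
# repeatedly zoomed around the incumbent minimum. Quadratic behaviour of the
# area near the optimum makes the final resolution (~4e-6 rad) good for
# ~1e-11 relative area error.

oracle_support <- function(H, theta) {
  M <- H %*% rbind(cos(theta), sin(theta))
  do.call(pmax, lapply(seq_len(nrow(H)), function(i) M[i, ]))
}

oracle_area <- function(H, th0, a, b) {
  th2 <- th0 + a
  th3 <- th0 + a + b
  h0 <- max(H %*% c(cos(th0), sin(th0)))
  h2 <- oracle_support(H, th2)
  h3 <- oracle_support(H, th3)
  isect <- function(t1, g1, t2, g2) {
    dt <- sin(t2 - t1)
    list(x = (g1 * sin(t2) - g2 * sin(t1)) / dt,
         y = (g2 * cos(t1) - g1 * cos(t2)) / dt)
  }
  v12 <- isect(th0, h0, th2, h2)
  v13 <- isect(th0, h0, th3, h3)
  v23 <- isect(th2, h2, th3, h3)
  area <- 0.5 * abs((v13$x - v12$x) * (v23$y - v12$y) -
                      (v23$x - v12$x) * (v13$y - v12$y))
  ok <- a > 1e-8 & a < pi - 1e-8 & b > 1e-8 & b < pi - 1e-8 &
    a + b > pi + 1e-8
  area[!ok | !is.finite(area)] <- Inf
  area
}

min_triangle_oracle <- function(points2d) {
  idx <- grDevices::chull(points2d)
  H <- as.matrix(points2d)[rev(idx), , drop = FALSE]
  m <- nrow(H)
  edge_normals <- vapply(seq_len(m), function(i) {
    e <- H[if (i == m) 1 else i + 1, ] - H[i, ]
    atan2(-e[1], e[2])
  }, numeric(1))
  best <- Inf
  for (i in seq_len(m)) {
    th0 <- edge_normals[i]
    lo_a <- 1e-4; hi_a <- pi - 1e-4
    lo_b <- 1e-4; hi_b <- pi - 1e-4
    step <- (hi_a - lo_a) / 120
    for (zoom in 1:5) {
      g <- expand.grid(a = seq(lo_a, hi_a, by = step),
                       b = seq(lo_b, hi_b, by = step))
      ar <- oracle_area(H, th0, g$a, g$b)
      j <- which.min(ar)
      if (!is.finite(ar[j])) break
      if (ar[j] < best) best <- ar[j]
      lo_a <- max(1e-4, g$a[j] - 2 * step); hi_a <- min(pi - 1e-4, g$a[j] + 2 * step)
      lo_b <- max(1e-4, g$b[j] - 2 * step); hi_b <- min(pi - 1e-4, g$b[j] + 2 * step)
      step <- step / 15
    }
  }
  best
}
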