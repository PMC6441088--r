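# --- 2-D geometry for the triangularity (Pareto) analysis ----------------

# counter-clockwise convex hull vertices
hull_ccw <- function(points2d) {
  P <- as.matrix(points2d)
  if (ncol(P) != 2 || nrow(P) < 3) stop("need >= 3 points in 2-D")
  idx <- grDevices::chull(P)        # clockwise order
  P[rev(idx), , drop = FALSE]
}

# shoelace area of a CCW polygon
shoelace <- function(V) {
  x <- V[, 1]; y <- V[, 2]
  0.5 * sum(x * (y[c(2:length(y), 1)]) - x[c(2:length(x), 1)] * y)
}

#' Area of the 2-D convex hull of a point set
#'
#' @param points2d n x 2 matrix of points (>= 3, not all collinear).
#' @return hull area (shoelace formula on the hull vertices).
#' @export
convex_hull_area <- function(points2d) {
  H <- hull_ccw(points2d)
  a <- shoelace(H)
  scale2 <- max(apply(points2d, 2, function(v) diff(range(v))))^2
  if (nrow(H) < 3 || a <= 1e-12 * max(scale2, .Machine$double.xmin)) {
    stop("degenerate input: points are collinear or coincident")
  }
  a
}

# support value of the hull in direction theta (max over vertices),
# vectorised over theta
hull_support <- function(H, theta) {
  M <- H %*% rbind(cos(theta), sin(theta))
  if (nrow(H) == 1) return(drop(M))
  out <- M[1, ]
  for (i in 2:nrow(H)) out <- pmax(out, M[i, ])
  out
}

# area of the triangle bounded by three support lines with outward normal
# angles th (vectorised over columns of a 3 x N angle matrix); Inf when the
# configuration is unbounded or degenerate
support_triangle_area <- function(H, th1, th2, th3) {
  h1 <- hull_support(H, th1); h2 <- hull_support(H, th2); h3 <- hull_support(H, th3)
  vx <- function(ta, ha, tb, hb) {
    dt <- sin(tb - ta)
    cbind((ha * sin(tb) - hb * sin(ta)) / dt,
          (hb * cos(ta) - ha * cos(tb)) / dt)
  }
  v12 <- vx(th1, h1, th2, h2)
  v13 <- vx(th1, h1, th3, h3)
  v23 <- vx(th2, h2, th3, h3)
  a <- 0.5 * abs((v13[, 1] - v12[, 1]) * (v23[, 2] - v12[, 2]) -
                   (v23[, 1] - v12[, 1]) * (v13[, 2] - v12[, 2]))
  # bounded iff the three normal angles do not fit in an open half-circle
  g1 <- (th2 - th1) %% (2 * pi)
  g2 <- (th3 - th2) %% (2 * pi)
  g3 <- 2 * pi - g1 - g2
  bad <- !(g1 > 1e-9 & g1 < pi - 1e-9 & g2 > 1e-9 & g2 < pi - 1e-9 &
             g3 > 1e-9 & g3 < pi - 1e-9)
  a[bad | !is.finite(a)] <- Inf
  a
}

# triangle vertices for one support-line triple
support_triangle_vertices <- function(H, th) {
  h <- vapply(th, function(t) hull_support(H, t), numeric(1))
  vx <- function(i, j) {
    dt <- sin(th[j] - th[i])
    c((h[i] * sin(th[j]) - h[j] * sin(th[i])) / dt,
      (h[j] * cos(th[i]) - h[i] * cos(th[j])) / dt)
  }
  rbind(vx(2, 3), vx(1, 3), vx(1, 2))
}

#' Minimal-area triangle enclosing a 2-D point set
#'
#' Finds the triangle of smallest area containing all points. At least one
#' side of the optimum is flush with a convex-hull edge, so the search
#' fixes each hull edge in turn as the flush side and minimises the area
#' over the outward-normal angles of the two remaining support lines
#' (coarse grid over the bounded-triangle region followed by Nelder-Mead
#' polishing from the best candidates, including all flush-edge pairs).
#'
#' @param points2d n x 2 matrix (>= 3 non-collinear points).
#' @param grid_step coarse search resolution in radians.
#' @param n_polish number of best grid candidates polished per flush edge.
#' @return list with `vertices` (3 x 2) and `area`.
#' @export
min_enclosing_triangle <- function(points2d, grid_step = pi / 90,
                                   n_polish = 6) {
  convex_hull_area(points2d)   # validates non-degeneracy
  H <- hull_ccw(points2d)
  m <- nrow(H)
  edge_normals <- vapply(seq_len(m), function(i) {
    e <- H[if (i == m) 1 else i + 1, ] - H[i, ]
    atan2(-e[1], e[2])         # outward normal of a CCW edge
  }, numeric(1))
  if (m == 3) {
    th <- sort(edge_normals %% (2 * pi))
    return(list(vertices = support_triangle_vertices(H, th),
                area = shoelace(hull_ccw(H))))
  }
  best <- list(area = Inf, th = NULL)
  ag <- seq(grid_step, pi - grid_step, by = grid_step)
  gr <- expand.grid(a = ag, b = ag)
  gr <- gr[gr$a + gr$b > pi + 1e-9, ]
  for (i in seq_len(m)) {
    th0 <- edge_normals[i]
    # candidate starts: coarse grid plus the other edges' normals
    oth <- sort((edge_normals[-i] - th0) %% (2 * pi))
    pairs <- if (length(oth) >= 2) {
      cmb <- utils::combn(oth, 2)
      data.frame(a = cmb[1, ], b = cmb[2, ] - cmb[1, ])
    } else NULL
    cand <- rbind(gr, pairs)
    area <- support_triangle_area(H, th0, th0 + cand$a, th0 + cand$a + cand$b)
    # polish the best candidates (flush-edge pairs are part of the pool and
    # already evaluated exactly)
    ord <- order(area)[seq_len(min(n_polish, length(area)))]
    h0 <- max(H[, 1] * cos(th0) + H[, 2] * sin(th0))
    c0 <- cos(th0); s0 <- sin(th0)
    fn <- function(p) {
      a <- p[1]; b <- p[2]
      if (a <= 1e-9 || a >= pi - 1e-9 || b <= 1e-9 || b >= pi - 1e-9 ||
          a + b <= pi + 1e-9) return(Inf)
      t2 <- th0 + a; t3 <- th0 + a + b
      c2 <- cos(t2); s2 <- sin(t2); c3 <- cos(t3); s3 <- sin(t3)
      h2 <- max(H[, 1] * c2 + H[, 2] * s2)
      h3 <- max(H[, 1] * c3 + H[, 2] * s3)
      d12 <- s2 * c0 - c2 * s0   # sin(t2 - th0)
      v12x <- (h0 * s2 - h2 * s0) / d12; v12y <- (h2 * c0 - h0 * c2) / d12
      d13 <- s3 * c0 - c3 * s0
      v13x <- (h0 * s3 - h3 * s0) / d13; v13y <- (h3 * c0 - h0 * c3) / d13
      d23 <- s3 * c2 - c3 * s2
      v23x <- (h2 * s3 - h3 * s2) / d23; v23y <- (h3 * c2 - h2 * c3) / d23
      0.5 * abs((v13x - v12x) * (v23y - v12y) - (v23x - v12x) * (v13y - v12y))
    }
    for (j in ord) {
      if (!is.finite(area[j])) next
      o <- stats::optim(c(cand$a[j], cand$b[j]), fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 400))
      if (o$value < best$area) {
        best <- list(area = o$value, th = c(th0, th0 + o$par[1],
                                            th0 + o$par[1] + o$par[2]))
      }
    }
  }
  verts <- support_triangle_vertices(H, best$th)
  list(vertices = verts, area = best$area)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Triangularity t-ratio of a 2-D point cloud
#'
#' Ratio of the convex-hull area to the area of the minimal enclosing
#' triangle; 1 means a perfectly triangular cloud. Invariant under
#' invertible affine maps of the points (both areas scale by the same
#' determinant).
#'
#' @inheritParams min_enclosing_triangle
#' @return object of class `t_ratio_result`: list with `hull_area`,
#'   `triangle_area`, `triangle_vertices`, `t_ratio`.
#' @export
t_ratio <- function(points2d, grid_step = pi / 90, n_polish = 6) {
  ha <- convex_hull_area(points2d)
  tri <- min_enclosing_triangle(points2d, grid_step = grid_step,
                                n_polish = n_polish)
  structure(list(hull_area = ha, triangle_area = tri$area,
                 triangle_vertices = tri$vertices,
                 t_ratio = ha / tri$area),
            class = "t_ratio_result")
}

#' @export
print.t_ratio_result <- function(x, ...) {
  cat("<t_ratio_result> hull area ", signif(x$hull_area, 6),
      ", min triangle area ", signif(x$triangle_area, 6),
      ", t-ratio ", signif(x$t_ratio, 6), sep = "")
  if (!is.null(x$p_value)) {
    cat(", p = ", signif(x$p_value, 4),
        if (isTRUE(x$significant)) " (significant)" else "", sep = "")
  }
  cat("\n")
  invisible(x)
}
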