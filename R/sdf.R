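# Signed distance to vessel lumina.
#
# All generated geometries are unions of circular-section vessels swept along
# polyline centerlines, so the signed distance to the wall is the minimum
# over vessels of (distance to centerline) - radius: negative inside the
# lumen, positive outside. This analytic form backs both grid classification
# for the flow solver and the marching-tetrahedra surface mesher.

# Distance from points (n x 3) to a polyline (k x 3); vectorized over points
# and segments.
dist_to_polyline <- function(pts, p) {
  nseg <- nrow(p) - 1
  d2 <- matrix(Inf, nrow(pts), nseg)
  for (s in seq_len(nseg)) {
    a <- p[s, ]; b <- p[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    w <- sweep(pts, 2, a)
    t <- if (len2 > 0) pmin(pmax((w %*% ab) / len2, 0), 1) else 0 * w[, 1]
    dx <- w - outer(as.vector(t), ab)
    d2[, s] <- rowSums(dx^2)
  }
  sqrt(apply(d2, 1, min))
}

# Signed distance of points to the union of a network's vessel lumina,
# optionally clipped by cap half-spaces (list of (point, outward normal)).
network_sdf <- function(spec, pts, caps = NULL) {
  pts <- matrix(pts, ncol = 3)
  d <- rep(Inf, nrow(pts))
  for (vs in spec$vessels) {
    d <- pmin(d, dist_to_polyline(pts, vs$centerline) - vs$diameter / 2)
  }
  if (!is.null(caps)) {
    for (cp in caps) {
      d <- pmax(d, sweep(pts, 2, cp$point) %*% cp$normal)
    }
  }
  as.vector(d)
}

# Numerical gradient of an SDF closure at points, central differences.
sdf_gradient <- function(phi, pts, eps = 1e-3) {
  g <- matrix(0, nrow(pts), 3)
  for (d in 1:3) {
    e <- matrix(0, 1, 3); e[d] <- eps
    g[, d] <- (phi(sweep(pts, 2, -e[1, ])) - phi(sweep(pts, 2, e[1, ]))) /
      (2 * eps)
  }
  g
}

#' Signed-distance field of a generated geometry
#'
#' Samples the analytic signed distance of a generated vessel geometry on a
#' uniform grid (negative inside the lumen) and keeps the analytic closure
#' for off-grid evaluation and wall projection.
#'
#' @param geom A `wall_mesh` with an attached `network_spec`, or a
#'   `network_spec` itself.
#' @param h Grid spacing, um; must satisfy `h <= min(diameter)/8`.
#' @param pad Margin added around the geometry bounding box, um.
#' @param bbox Optional 2 x 3 matrix (min row, max row) overriding the box.
#' @return A `distance_field`: grid axes, array of signed distances, spacing,
#'   and the closure `phi(pts)`.
#' @export
signed_distance <- function(geom, h, pad = 2, bbox = NULL) {
  spec <- if (inherits(geom, "wall_mesh")) geom$spec else geom
  if (is.null(spec)) stop("geometry carries no network_spec")
  dmin <- min(vapply(spec$vessels, function(v) v$diameter, 0))
  if (h > dmin / 8 + 1e-12)
    stop(sprintf("h = %.3g um too coarse: must be <= min diameter/8 = %.3g um",
                 h, dmin / 8))
  if (is.null(bbox)) {
    allp <- do.call(rbind, lapply(spec$vessels, function(v) v$centerline))
    rmax <- max(vapply(spec$vessels, function(v) v$diameter, 0)) / 2
    bbox <- rbind(apply(allp, 2, min) - rmax - pad,
                  apply(allp, 2, max) + rmax + pad)
  }
  ax <- lapply(1:3, function(d) seq(bbox[1, d], bbox[2, d], by = h))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  phi <- function(p) network_sdf(spec, p)
  vals <- array(phi(pts), dim = c(length(ax[[1]]), length(ax[[2]]),
                                  length(ax[[3]])))
  structure(list(axes = ax, values = vals, h = h, phi = phi, spec = spec,
                 bbox = bbox), class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %s grid, h = %.3g um, lumen fraction %.2f\n",
              paste(dim(x$values), collapse = "x"), x$h,
              mean(x$values < 0)))
  invisible(x)
}

# --- marching tetrahedra ----------------------------------------------------

# Corner offsets of a cube, numbered 1..8.
.mt_corner <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
# 6-tetrahedra decomposition around the 1-7 diagonal.
.mt_tets <- rbind(
  c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
  c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))

# Extract the zero iso-surface of f sampled on the uniform grid with axes ax
# as a welded triangle mesh (marching tetrahedra).
marching_tetrahedra <- function(vals, ax) {
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  cid <- as.matrix(expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1),
                               k = seq_len(nz - 1)))
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny
  corners <- sapply(1:8, function(c8)
    lin(cid[, 1] + .mt_corner[c8, 1], cid[, 2] + .mt_corner[c8, 2],
        cid[, 3] + .mt_corner[c8, 3]))
  v <- as.vector(vals)
  tri_a <- integer(0); tri_b <- integer(0); tri_c <- integer(0)
  # edge vertices identified by global grid-node pair (lo, hi)
  e_lo <- integer(0); e_hi <- integer(0)
  emit <- function(pairs) {
    # pairs: n x 6 matrix (a_lo,a_hi,b_lo,b_hi,c_lo,c_hi); returns indices
    n0 <- length(e_lo)
    e_lo <<- c(e_lo, pairs[, 1], pairs[, 3], pairs[, 5])
    e_hi <<- c(e_hi, pairs[, 2], pairs[, 4], pairs[, 6])
    n <- nrow(pairs)
    cbind(n0 + seq_len(n), n0 + n + seq_len(n), n0 + 2 * n + seq_len(n))
  }
  for (t6 in 1:6) {
    tc <- corners[, .mt_tets[t6, ], drop = FALSE]   # n_cubes x 4 node ids
    fv <- matrix(v[tc], ncol = 4)
    ins <- fv < 0
    k <- rowSums(ins)
    # one corner inside (or outside): single triangle
    for (mode in c("in1", "out1")) {
      sel <- which(if (mode == "in1") k == 1 else k == 3)
      if (!length(sel)) next
      m <- if (mode == "in1") ins[sel, , drop = FALSE] else !ins[sel, , drop = FALSE]
      apex <- max.col(m)                       # the lone corner
      oth <- t(vapply(apex, function(a) setdiff(1:4, a), integer(3)))
      g <- function(colsel) tc[sel, , drop = FALSE][cbind(seq_along(sel), colsel)]
      aidx <- g(apex)
      pairs <- cbind(aidx, g(oth[, 1]), aidx, g(oth[, 2]), aidx, g(oth[, 3]))
      id3 <- emit(pairs)
      tri_a <- c(tri_a, id3[, 1]); tri_b <- c(tri_b, id3[, 2])
      tri_c <- c(tri_c, id3[, 3])
    }
    # two in, two out: quad split into two triangles
    sel <- which(k == 2)
    if (length(sel)) {
      m <- ins[sel, , drop = FALSE]
      i1 <- max.col(m, ties.method = "first")
      i2 <- max.col(m, ties.method = "last")
      o12 <- t(vapply(seq_along(sel),
                      function(r) setdiff(1:4, c(i1[r], i2[r])), integer(2)))
      g <- function(colsel) tc[sel, , drop = FALSE][cbind(seq_along(sel), colsel)]
      A <- cbind(g(i1), g(o12[, 1])); B <- cbind(g(i1), g(o12[, 2]))
      C <- cbind(g(i2), g(o12[, 2])); D <- cbind(g(i2), g(o12[, 1]))
      id3 <- emit(cbind(A, B, C))
      tri_a <- c(tri_a, id3[, 1]); tri_b <- c(tri_b, id3[, 2])
      tri_c <- c(tri_c, id3[, 3])
      id3 <- emit(cbind(A, C, D))
      tri_a <- c(tri_a, id3[, 1]); tri_b <- c(tri_b, id3[, 2])
      tri_c <- c(tri_c, id3[, 3])
    }
  }
  if (!length(tri_a)) stop("iso-surface not found in grid")
  key_lo <- pmin(e_lo, e_hi); key_hi <- pmax(e_lo, e_hi)
  key <- paste(key_lo, key_hi)
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  lo <- key_lo[uk]; hi <- key_hi[uk]
  # interpolate vertex positions along grid edges
  node_xyz <- function(id) {
    id0 <- id - 1L
    i <- id0 %% nx
    j <- (id0 %/% nx) %% ny
    kk <- id0 %/% (nx * ny)
    cbind(ax[[1]][i + 1], ax[[2]][j + 1], ax[[3]][kk + 1])
  }
  plo <- node_xyz(lo); phi_ <- node_xyz(hi)
  flo <- v[lo]; fhi <- v[hi]
  t <- flo / (flo - fhi)
  t[!is.finite(t)] <- 0.5
  verts <- plo + (phi_ - plo) * t
  tr <- cbind(map[tri_a], map[tri_b], map[tri_c])
  # drop degenerate triangles (two welded vertices equal)
  keep <- tr[, 1] != tr[, 2] & tr[, 2] != tr[, 3] & tr[, 1] != tr[, 3]
  list(vertices = verts, triangles = tr[keep, , drop = FALSE])
}

# Orient every triangle so its normal aligns with the outward SDF gradient.
orient_outward <- function(mm, phi) {
  v <- mm$vertices; tr <- mm$triangles
  cen <- (v[tr[, 1], ] + v[tr[, 2], ] + v[tr[, 3], ]) / 3
  n <- vec_cross(v[tr[, 2], ] - v[tr[, 1], ], v[tr[, 3], ] - v[tr[, 1], ])
  g <- sdf_gradient(phi, cen)
  flip <- rowSums(n * g) < 0
  tr[flip, ] <- tr[flip, c(1, 3, 2)]
  mm$triangles <- tr
  mm
}
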