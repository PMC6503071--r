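# Triangulated vessel-wall surfaces.
#
# A `wall_mesh` is a list with:
#   vertices    n x 3 positions in um
#   triangles   m x 3 vertex indices (outward winding)
#   normals     n x 3 outward unit normals
#   vertex_area barycentric area weight per vertex, um^2
#   roi         character per vertex: "vessel:<id>", "bifurcation:<id>",
#               "convergence:<id>" or "cap"
#   spec        the network_spec that generated it (when available)

new_wall_mesh <- function(vertices, triangles, normals, roi, spec = NULL) {
  va <- vertex_areas(vertices, triangles)
  structure(list(vertices = vertices, triangles = triangles,
                 normals = normals, vertex_area = va, roi = roi,
                 spec = spec), class = "wall_mesh")
}

#' @export
print.wall_mesh <- function(x, ...) {
  cat(sprintf("<wall_mesh> %d vertices, %d triangles, area %.1f um^2, ROIs: %s\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$vertex_area),
              paste(unique(x$roi), collapse = ", ")))
  invisible(x)
}

triangle_areas <- function(v, tr) {
  cr <- vec_cross(v[tr[, 2], ] - v[tr[, 1], ], v[tr[, 3], ] - v[tr[, 1], ])
  0.5 * sqrt(rowSums(cr^2))
}

# Barycentric vertex areas: one third of each incident triangle area.
vertex_areas <- function(v, tr) {
  A <- triangle_areas(v, tr)
  va <- numeric(nrow(v))
  for (k in 1:3) va <- va + accum_vector(tr[, k], A / 3, nrow(v))
  va
}

#' Total surface area of a wall mesh
#' @param mesh A `wall_mesh`.
#' @return Area in um^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$triangles))

# Edge incidence audit. Returns counts of triangles sharing each undirected
# edge; a surface closed except at caps has every edge on 1 (boundary) or 2
# triangles.
edge_use_counts <- function(tr) {
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Check watertightness of a triangulated surface
#'
#' A mesh is watertight (closed) when every undirected edge is shared by
#' exactly two triangles; open caps show up as boundary edges used once.
#'
#' @param mesh A `wall_mesh` or a list with `triangles`.
#' @return List with `closed` (logical), `n_boundary_edges`, and
#'   `n_nonmanifold_edges` (edges used more than twice).
#' @export
check_watertight <- function(mesh) {
  cnt <- edge_use_counts(mesh$triangles)
  list(closed = all(cnt == 2L),
       n_boundary_edges = sum(cnt == 1L),
       n_nonmanifold_edges = sum(cnt > 2L))
}

#' Euler characteristic V - E + F of a triangulated surface
#' @param mesh A `wall_mesh` or list with `vertices` and `triangles`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nV <- length(unique(as.vector(tr)))
  nE <- length(unique(key))
  nF <- nrow(tr)
  nV - nE + nF
}

# Resample a polyline (k x 3) to ns+1 stations equally spaced in arc length.
# Returns positions, unit tangents and cumulative arc length.
resample_centerline <- function(p, ns) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  st <- seq(0, s[length(s)], length.out = ns + 1)
  pos <- sapply(1:3, function(d) approx(s, p[, d], xout = st)$y)
  tan <- rbind(pos[2, ] - pos[1, ],
               (pos[-(1:2), , drop = FALSE] - pos[1:(ns - 1), , drop = FALSE]) / 2,
               pos[ns + 1, ] - pos[ns, ])
  tan <- tan / sqrt(rowSums(tan^2))
  list(pos = pos, tangent = tan, arc = st, length = s[length(s)])
}

#' Arc length of a polyline by quadrature
#' @param p Polyline vertices, k x 3.
#' @return Total length (um).
#' @export
polyline_length <- function(p) {
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Generate a straight or curved tube wall mesh
#'
#' Sweeps a circular cross-section of the given diameter along a centerline,
#' producing an open-ended structured triangulation with parallel-transported
#' frames (no twist). The centerline runs along z; `curvature_profile`, when
#' given, displaces it laterally as a function of axial position.
#'
#' @param diameter Lumen diameter, um (4--30).
#' @param length Axial extent, um.
#' @param curvature_profile `NULL` for a straight tube, or a function
#'   `f(z)` returning the lateral x-displacement (um) of the centerline at
#'   axial position `z` in `[0, length]`.
#' @param mesh_size Target triangle edge length, um; must be < diameter/6.
#' @param id Vessel id used for the ROI label.
#' @param center `(x, y)` position of the axis, um.
#' @return A `wall_mesh` with an attached single-vessel `network_spec`. The
#'   structured parametrization is kept in attributes `rings` and `ntheta`,
#'   and per-vertex axial arc length `s_coord` and angle `theta_coord`.
#' @export
make_tube <- function(diameter, length, curvature_profile = NULL,
                      mesh_size = diameter / 12, id = 1, center = c(0, 0)) {
  if (diameter < 4 || diameter > 30)
    stop("diameter must be in [4, 30] um")
  if (mesh_size >= diameter / 6)
    stop(sprintf(
      "mesh_size (%.3g um) too coarse: must be < diameter/6 = %.3g um",
      mesh_size, diameter / 6))
  R <- diameter / 2
  nz <- max(4L, ceiling(length / mesh_size))
  ntheta <- max(8L, ceiling(pi * diameter / mesh_size))
  z <- seq(0, length, length.out = nz + 1)
  if (is.null(curvature_profile)) {
    cl <- cbind(center[1], center[2], z)
  } else {
    cl <- cbind(center[1] + vapply(z, curvature_profile, 0), center[2], z)
  }
  cl <- resample_centerline(cl, nz)
  th <- (seq_len(ntheta) - 1) / ntheta * 2 * pi
  # parallel transport an initial normal frame along the centerline
  tvec <- cl$tangent
  n1 <- matrix(0, nz + 1, 3)
  ref <- c(0, 1, 0)
  n1[1, ] <- ref - sum(ref * tvec[1, ]) * tvec[1, ]
  n1[1, ] <- n1[1, ] / sqrt(sum(n1[1, ]^2))
  for (i in 2:(nz + 1)) {
    v <- n1[i - 1, ] - sum(n1[i - 1, ] * tvec[i, ]) * tvec[i, ]
    n1[i, ] <- v / sqrt(sum(v^2))
  }
  n2 <- vec_cross(tvec, n1)
  nv <- (nz + 1) * ntheta
  verts <- matrix(0, nv, 3)
  norms <- matrix(0, nv, 3)
  s_coord <- numeric(nv)
  th_coord <- numeric(nv)
  for (i in seq_len(nz + 1)) {
    idx <- (i - 1) * ntheta + seq_len(ntheta)
    dir <- outer(cos(th), n1[i, ]) + outer(sin(th), n2[i, ])
    verts[idx, ] <- matrix(cl$pos[i, ], ntheta, 3, byrow = TRUE) + R * dir
    norms[idx, ] <- dir
    s_coord[idx] <- cl$arc[i]
    th_coord[idx] <- th
  }
  # quad ring i..i+1 split into triangles, outward winding
  tr <- matrix(0L, 2 * nz * ntheta, 3)
  row <- 1L
  for (i in seq_len(nz)) {
    a <- (i - 1) * ntheta + seq_len(ntheta)
    b <- (i - 1) * ntheta + c(seq_len(ntheta)[-1], 1L)
    cx <- a + ntheta
    d <- b + ntheta
    tr[row:(row + ntheta - 1), ] <- cbind(a, b, cx)
    tr[(row + ntheta):(row + 2 * ntheta - 1), ] <- cbind(b, d, cx)
    row <- row + 2L * ntheta
  }
  spec <- network_spec(
    vessels = list(list(id = id, centerline = cl$pos, diameter = diameter,
                        order = 1L, class = "capillary")),
    junctions = list(), inlet = id, outlet = id, horton_ratio = NA_real_,
    validate = FALSE)
  m <- new_wall_mesh(verts, tr, norms, rep(paste0("vessel:", id), nv), spec)
  attr(m, "rings") <- nz + 1
  attr(m, "ntheta") <- ntheta
  m$s_coord <- s_coord
  m$theta_coord <- th_coord
  m$centerline <- cl
  m
}
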