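#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# Subdivided icosahedron on the unit sphere. Returns vertices (n x 3, unit
# radius) and triangles (m x 3, 1-based, outward-wound).
icosphere <- function(n_refine) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  tr <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(n_refine)) {
    ne <- nrow(tr)
    # midpoint of each edge, deduplicated via keys
    e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    uk <- !duplicated(key)
    eu <- e[uk, , drop = FALSE]
    mid <- (v[eu[, 1], ] + v[eu[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- nrow(v) + match(key, key[uk])
    v <- rbind(v, mid)
    m12 <- midx[seq_len(ne)]
    m23 <- midx[ne + seq_len(ne)]
    m31 <- midx[2 * ne + seq_len(ne)]
    tr <- rbind(
      cbind(tr[, 1], m12, m31),
      cbind(m12, tr[, 2], m23),
      cbind(m31, m23, tr[, 3]),
      cbind(m12, m23, m31))
  }
  list(vertices = v, triangles = tr)
}

# Evans-Fung biconcave profile: half-thickness z/R0 as a function of the
# normalized cylindrical radius q = rho/R0, with R0 the cell radius.
biconcave_profile <- function(q, a0 = 0.207, a1 = 2.003, a2 = -1.123) {
  0.5 * sqrt(pmax(1 - q^2, 0)) * (a0 + a1 * q^2 + a2 * q^4)
}

#' Construct a biconcave red blood cell membrane
#'
#' Builds a closed triangulated membrane with the canonical biconcave
#' discocyte resting shape (Evans--Fung profile), stores the resting-shape
#' reference metrics used by the elastic force operators, and attaches the
#' elastic moduli.
#'
#' @param end_to_end Maximal in-plane diameter of the resting cell in um
#'   (default 7.8, giving a surface area of about 134.1 um^2 and volume of
#'   about 94.1 um^3).
#' @param n_refine Icosphere subdivision level (>= 2) before mapping onto the
#'   biconcave surface; level 5 gives 10242 vertices.
#' @param G_s Membrane shear modulus, N/m.
#' @param C_dil Dimensionless dilation-stiffness ratio of the Skalak law.
#' @param k_b Bending modulus, J.
#' @param c0 Spontaneous curvature, 1/um.
#' @param mu_interior Viscosity of the enclosed fluid (hemoglobin), Pa s.
#' @param sphere If `TRUE`, skip the biconcave mapping and return the unit
#'   sphere scaled by `end_to_end/2` (degenerate path used for closed-form
#'   checks).
#' @return An object of class `cell_membrane`: vertices (um), triangles,
#'   per-triangle reference edge geometry, moduli, reference area and volume.
#' @export
make_biconcave <- function(end_to_end = 7.8, n_refine = 4,
                           G_s = 2.5e-6, C_dil = 100, k_b = 2.7e-19, c0 = 0,
                           mu_interior = 0.005, sphere = FALSE) {
  stopifnot(n_refine >= 2)
  ico <- icosphere(n_refine)
  R0 <- end_to_end / 2
  if (sphere) {
    v <- ico$vertices * R0
  } else {
    q <- sqrt(ico$vertices[, 1]^2 + ico$vertices[, 2]^2)
    q <- pmin(q, 1)
    z <- sign(ico$vertices[, 3]) * biconcave_profile(q) * R0
    v <- cbind(R0 * ico$vertices[, 1], R0 * ico$vertices[, 2], z)
  }
  cell <- structure(list(
    vertices = v, triangles = ico$triangles,
    G_s = G_s, C_dil = C_dil, k_b = k_b, c0 = c0,
    mu_interior = mu_interior), class = "cell_membrane")
  cell$ref <- triangle_reference(v, ico$triangles)
  av <- area_volume(cell)
  cell$ref_area <- av[["area"]]
  cell$ref_volume <- av[["volume"]]
  cell
}

# Per-triangle reference geometry for the Skalak operator: squared edge
# lengths and reference area of every triangle of the resting shape.
triangle_reference <- function(v, tr) {
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e3 <- v[tr[, 3], , drop = FALSE] - v[tr[, 2], , drop = FALSE]
  cr <- vec_cross(e1, e2)
  A <- 0.5 * sqrt(rowSums(cr^2))
  if (any(A <= 0)) stop("degenerate reference triangle")
  list(l1sq = rowSums(e1^2), l2sq = rowSums(e2^2), l3sq = rowSums(e3^2),
       area = A)
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Surface area and enclosed volume of a closed triangulated surface
#'
#' Area is the sum of triangle areas; volume is the sum of signed tetrahedra
#' about the origin, which is translation invariant for a closed,
#' consistently wound surface.
#'
#' @param cell A `cell_membrane` (or any list with `vertices`/`triangles`).
#' @param vertices Optional deformed vertex array overriding `cell$vertices`.
#' @return Named numeric vector with elements `area` (um^2) and `volume`
#'   (um^3).
#' @export
area_volume <- function(cell, vertices = NULL) {
  v <- if (is.null(vertices)) cell$vertices else vertices
  tr <- cell$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  ccc <- v[tr[, 3], , drop = FALSE]
  cr <- vec_cross(b - a, ccc - a)
  area <- 0.5 * sum(sqrt(rowSums(cr^2)))
  vol <- sum(rowSums(a * vec_cross(b, ccc))) / 6
  if (vol < 0) stop("inconsistent triangle orientation (negative volume)")
  c(area = area, volume = vol)
}

#' @export
print.cell_membrane <- function(x, ...) {
  cat(sprintf(
    "<cell_membrane> %d vertices, %d triangles, area %.1f um^2, volume %.1f um^3\n",
    nrow(x$vertices), nrow(x$triangles), x$ref_area, x$ref_volume))
  invisible(x)
}
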