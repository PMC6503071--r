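# Membrane elastic and bending force densities.
#
# Both operators return minus the exact gradient of a discrete energy with
# respect to vertex positions, so total force and torque vanish to rounding
# and a finite-difference oracle reproduces every component.
#
# In-plane (Skalak) law: per triangle, the strain invariants are computed
# from the deformed and reference Gram matrices of the edge vectors, which
# depend only on squared edge lengths; the energy is therefore exactly
# invariant under rigid motions and its gradient has a short closed form.
#   W = Gs/4 (I1^2 + 2 I1 - 2 I2) + Gs C/4 I2^2,  per unit reference area.
#
# Bending (Helfrich) energy: E = kb/2 sum_i A_i (2H_i - c0)^2 with the mean
# curvature from the cotangent Laplacian and barycentric vertex areas.
# Positions enter through the cot weights, the edge differences and the
# areas; all three dependency paths are differentiated analytically.

.UM <- 1e-6  # um -> m

# Gram-matrix quantities from squared deformed edge lengths.
skalak_invariants <- function(ref, M1, M2, M3) {
  L1 <- ref$l1sq; L2 <- ref$l2sq; L3 <- ref$l3sq
  g0 <- (L1 + L2 - L3) / 2
  g <- (M1 + M2 - M3) / 2
  det0 <- L1 * L2 - g0^2
  I1 <- (L2 * M1 + L1 * M2 - 2 * g0 * g) / det0 - 2
  I2 <- (M1 * M2 - g^2) / det0 - 1
  list(I1 = I1, I2 = I2, g = g, g0 = g0, det0 = det0)
}

#' Skalak in-plane elastic energy and nodal forces
#'
#' Computes the finite-element in-plane membrane response of a red-cell
#' membrane under the Skalak strain-energy law (shear plus area-dilation
#' resistance), relative to the stored resting-shape reference metrics.
#' Nodal forces are minus the exact gradient of the discrete energy, so they
#' vanish identically at the reference shape and under rigid motions.
#'
#' @param cell A `cell_membrane`.
#' @param vertices Optional deformed vertex positions (um); defaults to the
#'   stored (reference) vertices.
#' @return List with `force` (n x 3, N), `energy` (J) and per-triangle
#'   invariants `I1`, `I2`.
#' @export
skalak_forces <- function(cell, vertices = NULL) {
  x <- (if (is.null(vertices)) cell$vertices else vertices) * .UM
  tr <- cell$triangles
  ref <- lapply(cell$ref[c("l1sq", "l2sq", "l3sq")], function(z) z * .UM^2)
  Aref <- cell$ref$area * .UM^2
  e1 <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e2 <- x[tr[, 3], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e3 <- x[tr[, 3], , drop = FALSE] - x[tr[, 2], , drop = FALSE]
  M1 <- rowSums(e1^2); M2 <- rowSums(e2^2); M3 <- rowSums(e3^2)
  if (any(M1 * M2 - ((M1 + M2 - M3) / 2)^2 <= 0))
    stop(sprintf("degenerate deformed triangle (first id %d)",
                 which(M1 * M2 - ((M1 + M2 - M3) / 2)^2 <= 0)[1]))
  iv <- skalak_invariants(ref, M1, M2, M3)
  Gs <- cell$G_s; Cd <- cell$C_dil
  Wd <- Gs / 4 * (iv$I1^2 + 2 * iv$I1 - 2 * iv$I2) + Gs * Cd / 4 * iv$I2^2
  energy <- sum(Aref * Wd)
  # dW/dI1, dW/dI2 per triangle
  dW1 <- Gs / 4 * (2 * iv$I1 + 2)
  dW2 <- -Gs / 2 + Gs * Cd / 2 * iv$I2
  L1 <- ref$l1sq; L2 <- ref$l2sq; g0 <- iv$g0; det0 <- iv$det0; g <- iv$g
  # dI/dMk
  dI1 <- cbind((L2 - g0), (L1 - g0), g0) / det0
  dI2 <- cbind((M2 - g), (M1 - g), g) / det0
  coef <- Aref * (dW1 * dI1 + dW2 * dI2)   # dE/dMk, k = 1..3
  f <- matrix(0, nrow(x), 3)
  add <- function(idx, val) {
    for (d in 1:3) f[, d] <<- f[, d] + accum_vector(idx, val[, d], nrow(x))
  }
  # M1 = |x2-x1|^2 etc.; dM/dx = +-2 * edge
  add(tr[, 2], -2 * coef[, 1] * e1); add(tr[, 1], 2 * coef[, 1] * e1)
  add(tr[, 3], -2 * coef[, 2] * e2); add(tr[, 1], 2 * coef[, 2] * e2)
  add(tr[, 3], -2 * coef[, 3] * e3); add(tr[, 2], 2 * coef[, 3] * e3)
  list(force = f, energy = energy, I1 = iv$I1, I2 = iv$I2)
}

# cot of the angle at apex between (a - apex) and (b - apex), plus the
# gradients of cot with respect to a and b (apex gradient is minus their sum).
cot_and_grads <- function(apex, a, b) {
  u <- a - apex; v <- b - apex
  cc <- vec_cross(u, v)
  n <- sqrt(rowSums(cc^2))
  uv <- rowSums(u * v)
  ct <- uv / n
  gu <- v / n - uv / n^3 * vec_cross(v, cc)
  gv <- u / n - uv / n^3 * vec_cross(cc, u)
  list(cot = ct, gu = gu, gv = gv)
}

#' Helfrich bending energy and nodal forces
#'
#' Discrete curvature-squared bending energy
#' `E = kb/2 * sum_i A_i (2 H_i - c0)^2` with the mean curvature magnitude
#' from the cotangent Laplacian and barycentric vertex areas. Forces are
#' minus the exact analytic gradient of this discrete energy.
#'
#' @inheritParams skalak_forces
#' @return List with `force` (n x 3, N), `energy` (J) and per-vertex mean
#'   curvature `H` (1/m).
#' @export
bending_forces <- function(cell, vertices = NULL) {
  x <- (if (is.null(vertices)) cell$vertices else vertices) * .UM
  tr <- cell$triangles
  kb <- cell$k_b
  c0 <- cell$c0 / .UM          # 1/um -> 1/m
  nv <- nrow(x)
  x1 <- x[tr[, 1], , drop = FALSE]
  x2 <- x[tr[, 2], , drop = FALSE]
  x3 <- x[tr[, 3], , drop = FALSE]
  ct1 <- cot_and_grads(x1, x2, x3)   # angle at v1, opposite edge (2,3)
  ct2 <- cot_and_grads(x2, x3, x1)   # angle at v2, opposite edge (3,1)
  ct3 <- cot_and_grads(x3, x1, x2)   # angle at v3, opposite edge (1,2)
  acc <- function(M, idx, val) {
    for (d in 1:3) M[, d] <- M[, d] + accum_vector(idx, val[, d], nv)
    M
  }
  accv <- function(vec, idx, val) vec + accum_vector(idx, val, nv)
  # S_i = sum_j w_ij (x_i - x_j), assembled triangle-wise
  S <- matrix(0, nv, 3)
  S <- acc(S, tr[, 2], ct1$cot * (x2 - x3)); S <- acc(S, tr[, 3], ct1$cot * (x3 - x2))
  S <- acc(S, tr[, 3], ct2$cot * (x3 - x1)); S <- acc(S, tr[, 1], ct2$cot * (x1 - x3))
  S <- acc(S, tr[, 1], ct3$cot * (x1 - x2)); S <- acc(S, tr[, 2], ct3$cot * (x2 - x1))
  # barycentric vertex areas
  cr <- vec_cross(x2 - x1, x3 - x1)
  At <- 0.5 * sqrt(rowSums(cr^2))
  A <- numeric(nv)
  for (k in 1:3) A <- accv(A, tr[, k], At / 3)
  Smag <- sqrt(rowSums(S^2))
  H2 <- Smag / (2 * A)               # 2H
  energy <- kb / 2 * sum(A * (H2 - c0)^2)
  # adjoints
  Shat <- S / pmax(Smag, 1e-300)
  a <- kb / 2 * (H2 - c0) * Shat     # dE/dS_i
  b <- -kb / 2 * (H2 - c0) * (H2 + c0)  # dE/dA_i (direct)
  grad <- matrix(0, nv, 3)
  a1 <- a[tr[, 1], ]; a2 <- a[tr[, 2], ]; a3 <- a[tr[, 3], ]
  # direct edge terms: edge (i,j) with weight w: grad_i += w (a_i - a_j), etc.
  grad <- acc(grad, tr[, 2], ct1$cot * (a2 - a3)); grad <- acc(grad, tr[, 3], ct1$cot * (a3 - a2))
  grad <- acc(grad, tr[, 3], ct2$cot * (a3 - a1)); grad <- acc(grad, tr[, 1], ct2$cot * (a1 - a3))
  grad <- acc(grad, tr[, 1], ct3$cot * (a1 - a2)); grad <- acc(grad, tr[, 2], ct3$cot * (a2 - a1))
  # cot-weight terms: gamma = (a_i - a_j) . (x_i - x_j) for the opposite edge
  g1 <- rowSums((a2 - a3) * (x2 - x3))
  g2 <- rowSums((a3 - a1) * (x3 - x1))
  g3 <- rowSums((a1 - a2) * (x1 - x2))
  grad <- acc(grad, tr[, 2], g1 * ct1$gu); grad <- acc(grad, tr[, 3], g1 * ct1$gv)
  grad <- acc(grad, tr[, 1], -g1 * (ct1$gu + ct1$gv))
  grad <- acc(grad, tr[, 3], g2 * ct2$gu); grad <- acc(grad, tr[, 1], g2 * ct2$gv)
  grad <- acc(grad, tr[, 2], -g2 * (ct2$gu + ct2$gv))
  grad <- acc(grad, tr[, 1], g3 * ct3$gu); grad <- acc(grad, tr[, 2], g3 * ct3$gv)
  grad <- acc(grad, tr[, 3], -g3 * (ct3$gu + ct3$gv))
  # area terms: grad_p A_t with weight (b_i + b_j + b_k)/3
  nhat <- cr / (2 * At)
  wt <- (b[tr[, 1]] + b[tr[, 2]] + b[tr[, 3]]) / 3
  gA2 <- vec_cross(x3 - x1, nhat) / 2
  gA3 <- vec_cross(nhat, x2 - x1) / 2
  gA1 <- -(gA2 + gA3)
  grad <- acc(grad, tr[, 1], wt * gA1)
  grad <- acc(grad, tr[, 2], wt * gA2)
  grad <- acc(grad, tr[, 3], wt * gA3)
  list(force = -grad, energy = energy, H = H2 / 2)
}

#' Total membrane force density
#'
#' Elastic (Skalak) plus bending (Helfrich) nodal forces on a cell membrane.
#'
#' @inheritParams skalak_forces
#' @return List with `force` (n x 3, N) and the two parts `elastic` and
#'   `bending`.
#' @export
membrane_forces <- function(cell, vertices = NULL) {
  el <- skalak_forces(cell, vertices)
  be <- bending_forces(cell, vertices)
  list(force = el$force + be$force, elastic = el$force, bending = be$force,
       energy = el$energy + be$energy, max_strain = max(abs(el$I1)))
}

# Finite-difference gradient of an energy function (oracle for tests).
fd_energy_gradient <- function(energy_fn, vertices, idx, step = 1e-7) {
  g <- matrix(0, length(idx), 3)
  for (r in seq_along(idx)) {
    for (d in 1:3) {
      vp <- vertices; vm <- vertices
      vp[idx[r], d] <- vp[idx[r], d] + step
      vm[idx[r], d] <- vm[idx[r], d] - step
      g[r, d] <- (energy_fn(vp) - energy_fn(vm)) / (2 * step)
    }
  }
  g
}
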