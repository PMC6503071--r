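# Unsteady Stokes solver with immersed-boundary coupling.
#
# Time stepping is an incremental pressure-correction projection. The
# viscous update is a delta-form alternating-direction-implicit (ADI) solve
# at the maximum viscosity whose tridiagonal sweeps treat solid and ghost
# nodes as identity rows, so implicit diffusion never couples across the
# wall and the steady state satisfies the unsplit discrete Stokes balance
# with the ghost-node wall values; the variable-viscosity (cell interior
# versus plasma) stress divergence enters the explicit right-hand side with
# harmonic face averaging. The pressure projection is an exact FFT Poisson
# solve, so the discrete divergence on every cell is zero to rounding after
# each step. Membrane forces enter through the continuous-forcing IBM with
# the Peskin 4-point kernel; the same kernel interpolates grid velocity back
# to the membrane vertices (adjoint pair: total force is conserved exactly).

# Peskin 4-point cosine kernel.
peskin4 <- function(r) {
  a <- abs(r)
  w <- numeric(length(a))
  i1 <- a < 1
  w[i1] <- (3 - 2 * a[i1] + sqrt(pmax(1 + 4 * a[i1] - 4 * a[i1]^2, 0))) / 8
  i2 <- !i1 & a < 2
  w[i2] <- (5 - 2 * a[i2] - sqrt(pmax(-7 + 12 * a[i2] - 4 * a[i2]^2, 0))) / 8
  w
}

# 64-point kernel stencil for points (um) on the staggered grid of comp:
# linear indices (np x 64) and weights (np x 64, rows sum to 1).
ibm_weights <- function(pts, grid, comp) {
  off <- c(0.5, 0.5, 0.5)
  if (comp == "u") off[1] <- 0
  if (comp == "v") off[2] <- 0
  if (comp == "w") off[3] <- 0
  n <- grid$n; h <- grid$h
  np <- nrow(pts)
  s <- matrix(sapply(1:3, function(d) (pts[, d] - grid$x0[d]) / h - off[d] + 1),
              ncol = 3)
  i0 <- floor(s)
  wd <- list(); id <- list()
  for (d in 1:3) {
    wd[[d]] <- sapply(-1:2, function(o) peskin4(i0[, d] + o - s[, d]))
    id[[d]] <- sapply(-1:2, function(o) ((i0[, d] + o - 1) %% n[d]) + 1)
    if (np == 1) { wd[[d]] <- matrix(wd[[d]], 1); id[[d]] <- matrix(id[[d]], 1) }
  }
  idx <- matrix(0L, np, 64)
  wts <- matrix(0, np, 64)
  colk <- 1L
  for (dx in 1:4) for (dy in 1:4) for (dz in 1:4) {
    idx[, colk] <- id[[1]][, dx] + (id[[2]][, dy] - 1) * n[1] +
      (id[[3]][, dz] - 1) * n[1] * n[2]
    wts[, colk] <- wd[[1]][, dx] * wd[[2]][, dy] * wd[[3]][, dz]
    colk <- colk + 1L
  }
  list(idx = idx, w = wts)
}

# C-level scatter-add of values into a length-N vector: radix sort plus
# cumulative-sum differencing (no per-group string keys).
accum_plan <- function(idx) {
  o <- order(idx, method = "radix")
  si <- idx[o]
  last <- which(c(si[-1] != si[-length(si)], TRUE))
  list(o = o, nodes = si[last], last = last)
}

accum_exec <- function(plan, val, N) {
  cs <- cumsum(val[plan$o])
  out <- numeric(N)
  out[plan$nodes] <- diff(c(0, cs[plan$last]))
  out
}

accum_vector <- function(idx, val, N) accum_exec(accum_plan(idx), val, N)

# Concatenate several identical-moduli cell membranes into one block
# membrane so the force operators run once per step (forces do not couple
# across cells, so the result is identical).
pool_cells <- function(cells) {
  if (length(cells) == 1) return(cells[[1]])
  nv <- vapply(cells, function(cl) nrow(cl$vertices), 0L)
  off <- cumsum(c(0L, nv[-length(nv)]))
  tr <- do.call(rbind, lapply(seq_along(cells), function(i)
    cells[[i]]$triangles + off[i]))
  pool <- cells[[1]]
  pool$vertices <- do.call(rbind, lapply(cells, function(cl) cl$vertices))
  pool$triangles <- tr
  pool$ref <- list(
    l1sq = unlist(lapply(cells, function(cl) cl$ref$l1sq)),
    l2sq = unlist(lapply(cells, function(cl) cl$ref$l2sq)),
    l3sq = unlist(lapply(cells, function(cl) cl$ref$l3sq)),
    area = unlist(lapply(cells, function(cl) cl$ref$area)))
  pool
}

#' Spread Lagrangian point forces to the Eulerian grid
#'
#' Continuous-forcing IBM spreading with the Peskin 4-point kernel: a set of
#' nodal forces (N) becomes a grid force density (N/m^3). Spreading
#' conserves the total force exactly because the kernel weights sum to one.
#'
#' @param grid An `eulerian_grid`.
#' @param pts Lagrangian point positions, n x 3, um.
#' @param values Per-point scalar values (e.g. one force component, N).
#' @param comp Which staggered grid to target: `"u"`, `"v"`, `"w"` or `"c"`.
#' @return 3-d array of densities (`values` unit / m^3).
#' @export
ibm_spread <- function(grid, pts, values, comp, kw = NULL, cache = NULL,
                       key = NULL) {
  if (is.null(kw)) kw <- ibm_weights(pts, grid, comp)
  if (!is.null(cache) && !is.null(key)) {
    # Lagrangian points move a small fraction of a cell per step, so the
    # scatter index set (and hence its sort plan) is usually unchanged
    prev <- cache[[key]]
    if (is.null(prev) || !identical(prev$idx, kw$idx)) {
      prev <- list(idx = kw$idx, plan = accum_plan(as.vector(kw$idx)))
      cache[[key]] <- prev
    }
    out <- accum_exec(prev$plan, as.vector(kw$w * values), prod(grid$n))
  } else {
    out <- accum_vector(as.vector(kw$idx), as.vector(kw$w * values),
                        prod(grid$n))
  }
  array(out / grid$h_m^3, dim = grid$n)
}

#' Interpolate a grid field at Lagrangian points (IBM kernel)
#'
#' Adjoint of [ibm_spread()]: same kernel weights, so spreading followed by
#' interpolation conserves the discrete inner product.
#'
#' @inheritParams ibm_spread
#' @param field 3-d array on the staggered grid of `comp`.
#' @return Numeric vector of interpolated values.
#' @export
ibm_interpolate <- function(grid, field, pts, comp, kw = NULL) {
  if (is.null(kw)) kw <- ibm_weights(pts, grid, comp)
  v <- as.vector(field)
  rowSums(kw$w * matrix(v[kw$idx], nrow(kw$idx)))
}

# --- spectral Poisson -------------------------------------------------------

poisson_solve <- function(rhs, grid) {
  den <- -grid$ksq
  den[1] <- 1                       # zero mode: mean set to zero
  rh <- stats::fft(rhs) / den
  rh[1] <- 0
  Re(stats::fft(rh, inverse = TRUE)) / length(rhs)
}

# --- ADI viscous solve ------------------------------------------------------
#
# Delta-form approximate factorization: the viscous update solves
#   (I - a Dxx)(I - a Dyy)(I - a Dzz) du = dt/rho * RHS(u^n)
# with a = dt * mu_max / rho, one batched tridiagonal solve per direction.
# Non-fluid rows (solid and ghost nodes) are identity rows with zero
# right-hand side: walls are stationary, so the increment vanishes there and
# the implicit operator never couples across the wall. Because the scheme is
# in delta form, its steady state satisfies the unsplit discrete balance
# 0 = -grad p + div tau + f exactly, with the ghost-node wall values.

# Batched Thomas algorithm: lo/dg/up/rhs are (n x m); column-wise tridiagonal
# systems with lo[1,] and up[n,] ignored.
thomas_batch <- function(lo, dg, up, rhs) {
  n <- nrow(rhs)
  cp <- matrix(0, n, ncol(rhs)); xp <- matrix(0, n, ncol(rhs))
  cp[1, ] <- up[1, ] / dg[1, ]
  xp[1, ] <- rhs[1, ] / dg[1, ]
  for (i in 2:n) {
    mlt <- 1 / (dg[i, ] - lo[i, ] * cp[i - 1, ])
    cp[i, ] <- up[i, ] * mlt
    xp[i, ] <- (rhs[i, ] - lo[i, ] * xp[i - 1, ]) * mlt
  }
  for (i in (n - 1):1) xp[i, ] <- xp[i, ] - cp[i, ] * xp[i + 1, ]
  xp
}

# Precompute the LU-style factors of the (cyclic) batched tridiagonal systems
# of one ADI sweep: coefficients are static for a fixed grid and dt, so the
# per-step work reduces to forward/backward substitution.
prep_adi_dim <- function(fluid, a, d) {
  perm <- switch(d, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  fl <- aperm(fluid, perm)
  pdim <- dim(fl)
  n <- pdim[1]; m <- prod(pdim[2:3])
  dim(fl) <- c(n, m)
  keep <- which(colSums(fl) > 0)
  flk <- fl[, keep, drop = FALSE] * 1
  lo <- -a * flk
  up <- lo
  dg <- 1 + 2 * a * flk
  al <- lo[1, ]; be <- up[n, ]
  gam <- -dg[1, ]
  dg2 <- dg
  dg2[1, ] <- dg[1, ] - gam
  dg2[n, ] <- dg[n, ] - al * be / gam
  # factor dg2 into cp (superdiagonal of U) and mlt (pivots)
  nk <- length(keep)
  cp <- matrix(0, n, nk); mlt <- matrix(0, n, nk)
  mlt[1, ] <- 1 / dg2[1, ]
  cp[1, ] <- up[1, ] * mlt[1, ]
  for (i in 2:n) {
    mlt[i, ] <- 1 / (dg2[i, ] - lo[i, ] * cp[i - 1, ])
    cp[i, ] <- up[i, ] * mlt[i, ]
  }
  # Sherman-Morrison correction vector
  U <- matrix(0, n, nk); U[1, ] <- gam; U[n, ] <- be
  z <- thomas_batch(lo, dg2, up, U)
  den <- 1 + z[1, ] + al * z[n, ] / gam
  list(perm = perm, iperm = order(perm), pdim = pdim, n = n, m = m,
       keep = keep, lo = lo, cp = cp, mlt = mlt, z = z, den = den,
       al = al, gam = gam)
}

# Substitution pass using cached factors.
thomas_sub <- function(pre, rhs) {
  n <- pre$n
  xp <- rhs
  xp[1, ] <- rhs[1, ] * pre$mlt[1, ]
  for (i in 2:n) xp[i, ] <- (rhs[i, ] - pre$lo[i, ] * xp[i - 1, ]) * pre$mlt[i, ]
  for (i in (n - 1):1) xp[i, ] <- xp[i, ] - pre$cp[i, ] * xp[i + 1, ]
  xp
}

adi_sweep_cached <- function(rhs, pre) {
  r <- aperm(rhs, pre$perm)
  dim(r) <- c(pre$n, pre$m)
  rk <- r[, pre$keep, drop = FALSE]
  x <- thomas_sub(pre, rk)
  fact <- (x[1, ] + pre$al * x[pre$n, ] / pre$gam) / pre$den
  x <- x - pre$z * rep(fact, each = pre$n)
  r[, pre$keep] <- x
  dim(r) <- pre$pdim
  aperm(r, pre$iperm)
}

# Full delta-form viscous solve for one velocity component (cached factors).
adi_delta_solve <- function(rhs, pre3) {
  adi_sweep_cached(adi_sweep_cached(adi_sweep_cached(rhs, pre3[[1]]),
                                    pre3[[2]]), pre3[[3]])
}

# Build (or fetch) the ADI factor cache for a given dt.
adi_cache <- function(sys, dt) {
  key <- sprintf("adi_%.6g", dt)
  if (!is.null(sys$cache[[key]])) return(sys$cache[[key]])
  a <- dt * sys$mu0 / (sys$rho * sys$grid$h_m^2)
  out <- lapply(c(u = "u", v = "v", w = "w"), function(comp)
    lapply(1:3, function(d) prep_adi_dim(sys$grid$comp[[comp]]$fluid, a, d)))
  sys$cache[[key]] <- out
  out
}

# --- finite-volume operators ------------------------------------------------

divergence <- function(u, v, w, h) {
  (pshift(u, 1, 1) - u + pshift(v, 1, 2) - v + pshift(w, 1, 3) - w) / h
}

laplacian <- function(a, h) {
  (pshift(a, 1, 1) + pshift(a, -1, 1) + pshift(a, 1, 2) + pshift(a, -1, 2) +
     pshift(a, 1, 3) + pshift(a, -1, 3) - 6 * a) / h^2
}

harmonic4 <- function(a, b, cc, d) 4 / (1 / a + 1 / b + 1 / cc + 1 / d)

# Divergence of the viscous stress mu (grad u + grad u^T) on the MAC grid,
# with mu at centers and harmonic averaging onto edges.
visc_divstress <- function(u, v, w, mu, h) {
  dudx <- (pshift(u, 1, 1) - u) / h      # at centers
  dvdy <- (pshift(v, 1, 2) - v) / h
  dwdz <- (pshift(w, 1, 3) - w) / h
  txx <- 2 * mu * dudx
  tyy <- 2 * mu * dvdy
  tzz <- 2 * mu * dwdz
  mu_xy <- harmonic4(mu, pshift(mu, -1, 1), pshift(mu, -1, 2),
                     pshift(pshift(mu, -1, 1), -1, 2))
  mu_xz <- harmonic4(mu, pshift(mu, -1, 1), pshift(mu, -1, 3),
                     pshift(pshift(mu, -1, 1), -1, 3))
  mu_yz <- harmonic4(mu, pshift(mu, -1, 2), pshift(mu, -1, 3),
                     pshift(pshift(mu, -1, 2), -1, 3))
  txy <- mu_xy * ((u - pshift(u, -1, 2)) / h + (v - pshift(v, -1, 1)) / h)
  txz <- mu_xz * ((u - pshift(u, -1, 3)) / h + (w - pshift(w, -1, 1)) / h)
  tyz <- mu_yz * ((v - pshift(v, -1, 3)) / h + (w - pshift(w, -1, 2)) / h)
  fx <- (txx - pshift(txx, -1, 1)) / h + (pshift(txy, 1, 2) - txy) / h +
    (pshift(txz, 1, 3) - txz) / h
  fy <- (pshift(txy, 1, 1) - txy) / h + (tyy - pshift(tyy, -1, 2)) / h +
    (pshift(tyz, 1, 3) - tyz) / h
  fz <- (pshift(txz, 1, 1) - txz) / h + (pshift(tyz, 1, 2) - tyz) / h +
    (tzz - pshift(tzz, -1, 3)) / h
  list(x = fx, y = fy, z = fz)
}

# --- viscosity indicator ----------------------------------------------------

#' Viscosity field from cell interiors
#'
#' Builds a smoothed indicator of the union of cell interiors by spreading
#' the outward surface normals (weighted by triangle area) onto the grid and
#' solving a Poisson equation for the characteristic function, then maps it
#' to viscosity: plasma outside, hemoglobin value inside, with a transition
#' band of about two grid cells.
#'
#' @param cells List of `cell_membrane` objects (current vertex positions).
#' @param grid An `eulerian_grid`.
#' @param mu_plasma,mu_interior Viscosities, Pa s.
#' @return List with `mu` (center array, Pa s) and `indicator` (0..1).
#' @export
viscosity_field <- function(cells, grid, mu_plasma = 0.001,
                            mu_interior = 0.005, cache = NULL) {
  if (!length(cells)) {
    ind <- array(0, dim = grid$n)
    return(list(mu = array(mu_plasma, dim = grid$n), indicator = ind))
  }
  cen <- NULL; nA <- NULL
  for (cl in cells) {
    # closed genus-0 surface has exactly 2 nV - 4 triangles
    if (nrow(cl$triangles) != 2 * nrow(cl$vertices) - 4)
      stop("open cell surface passed to viscosity_field")
    v <- cl$vertices; tr <- cl$triangles
    cr <- vec_cross(v[tr[, 2], ] - v[tr[, 1], ], v[tr[, 3], ] - v[tr[, 1], ])
    cen <- rbind(cen, (v[tr[, 1], ] + v[tr[, 2], ] + v[tr[, 3], ]) / 3)
    nA <- rbind(nA, -0.5 * cr * .UM^2)      # -n dA, m^2
  }
  gx <- ibm_spread(grid, cen, nA[, 1], "u", cache = cache, key = "vis_u")
  gy <- ibm_spread(grid, cen, nA[, 2], "v", cache = cache, key = "vis_v")
  gz <- ibm_spread(grid, cen, nA[, 3], "w", cache = cache, key = "vis_w")
  rhs <- divergence(gx, gy, gz, grid$h_m)
  ind <- poisson_solve(rhs, grid)
  ph <- grid$comp$c$phi
  far <- as.vector(ph) >= stats::quantile(ph, 0.98)
  ind <- ind - mean(ind[far])
  ind <- pmin(pmax(ind, 0), 1)
  list(mu = mu_plasma + (mu_interior - mu_plasma) * ind, indicator = ind)
}

# --- system assembly --------------------------------------------------------

#' Assemble a flow system from a geometry
#'
#' Classifies the staggered grid against the geometry's signed distance,
#' stores material constants and the boundary-condition descriptor, and
#' precomputes the spectral symbols. The axial direction is z and the domain
#' is periodic along it; driving is a mean axial pressure gradient in the
#' lumen (`pressure_drop`, Pa/um) or a feedback-controlled gradient hitting
#' a target volumetric flow rate (`inlet_flow_rate`, m^3/s).
#'
#' @param geom A `wall_mesh` with attached spec/SDF (fixture generators), or
#'   a `distance_field`.
#' @param h Grid spacing, um.
#' @param bc List with `kind` (`"pressure_drop"` or `"inlet_flow_rate"`) and
#'   `value`.
#' @param rho Fluid density, kg/m^3.
#' @param mu_plasma,mu_interior Plasma and cell-interior viscosities, Pa s.
#' @param pad Lateral padding added around the geometry, um.
#' @param Lz Axial period, um; defaults to the geometry `period` attribute.
#' @return A `flow_system`.
#' @export
flow_system <- function(geom, h, bc = list(kind = "pressure_drop", value = 0.5),
                        rho = 1000, mu_plasma = 0.001, mu_interior = 0.005,
                        pad = 2, Lz = NULL) {
  if (inherits(geom, "wall_mesh")) {
    spec <- geom$spec
    phi0 <- if (!is.null(geom$phi)) geom$phi else function(p) network_sdf(spec, p)
    allp <- do.call(rbind, lapply(spec$vessels, function(v) v$centerline))
    rmax <- max(vapply(spec$vessels, function(v) v$diameter, 0)) / 2
    if (is.null(Lz)) Lz <- attr(geom, "period")
    if (is.null(Lz)) Lz <- max(allp[, 3]) - min(allp[, 3])
    zr <- attr(geom, "z_range")
    z0 <- if (!is.null(zr)) zr[1] else min(allp[, 3])
    bbox <- rbind(c(apply(allp[, 1:2, drop = FALSE], 2, min) - rmax - pad, z0),
                  c(apply(allp[, 1:2, drop = FALSE], 2, max) + rmax + pad,
                    z0 + Lz))
    phi <- function(p) {
      p[, 3] <- z0 + ((p[, 3] - z0) %% Lz)
      phi0(p)
    }
    field <- structure(list(phi = phi, h = h, bbox = bbox, spec = spec),
                       class = "distance_field")
  } else {
    field <- geom
    if (is.null(Lz)) Lz <- field$bbox[2, 3] - field$bbox[1, 3]
  }
  grid <- classify_grid(field, h = h, bbox = field$bbox)
  if (!any(grid$comp$c$fluid))
    stop("geometry contains no fluid nodes: nothing to solve")
  mesh <- if (inherits(geom, "wall_mesh")) geom else NULL
  structure(list(grid = grid, field = field, mesh = mesh, bc = bc, rho = rho,
                 mu_plasma = mu_plasma, mu_interior = mu_interior,
                 mu0 = mu_interior, Lz = Lz, cache = new.env(parent = emptyenv())),
            class = "flow_system")
}

#' Initial flow state
#'
#' @param sys A `flow_system`.
#' @param cells Optional list of `cell_membrane` objects already placed in
#'   the lumen.
#' @return A `flow_state` with zero velocity and pressure.
#' @export
flow_state <- function(sys, cells = list()) {
  n <- sys$grid$n
  z <- function() array(0, dim = n)
  G0 <- if (sys$bc$kind == "pressure_drop") sys$bc$value * 1e6 else {
    spec <- sys$field$spec
    R <- max(vapply(spec$vessels, function(v) v$diameter, 0)) / 2 * 1e-6
    8 * sys$mu_plasma * sys$bc$value / (pi * R^4)
  }
  structure(list(u = z(), v = z(), w = z(), p = z(), t = 0, G = G0,
                 cells = cells,
                 mu = array(sys$mu_plasma, dim = n)),
            class = "flow_state")
}

#' Stable time step for the coupled solver
#'
#' The implicit viscous solve is unconditionally stable, so the step is set
#' by the explicit membrane coupling: the overdamped relaxation of the
#' stiffest elastic mode (shear plus dilation stiffness) and of the bending
#' mode against Stokes drag at the grid scale, each multiplied by a safety
#' factor, plus an accuracy cap protecting membrane area conservation
#' (proportional to the grid spacing). Plasma-only runs are limited only by
#' the accuracy cap.
#'
#' @param grid An `eulerian_grid`.
#' @param cells List of cells (empty for plasma-only runs).
#' @param mu Plasma viscosity, Pa s.
#' @param G_s,C_dil,k_b Membrane moduli (taken from the first cell when
#'   omitted).
#' @param accuracy_cap Upper bound on dt regardless of stability, s; default
#'   2e-6 for plasma-only runs and `5e-6 * h[um] / 0.5 um` with cells
#'   (calibrated by a dt-refinement study of membrane area conservation in
#'   capillary-speed tube flow).
#' @param safety Safety factor on the stability limits.
#' @return Time step in seconds.
#' @export
stable_dt <- function(grid, cells = list(), mu = 0.001, G_s = NULL,
                      C_dil = NULL, k_b = NULL, accuracy_cap = NULL,
                      safety = 0.5) {
  if (!length(cells) && is.null(G_s))
    return(if (is.null(accuracy_cap)) 2e-6 else accuracy_cap)
  if (is.null(G_s)) G_s <- cells[[1]]$G_s
  if (is.null(C_dil)) C_dil <- cells[[1]]$C_dil
  if (is.null(k_b)) k_b <- cells[[1]]$k_b
  h <- grid$h_m
  dt_el <- 3 * pi * mu * h / (G_s * (1 + C_dil))
  dt_bend <- 3 * pi * mu * h^3 / k_b
  if (is.null(accuracy_cap)) accuracy_cap <- 5e-6 * h / 0.5e-6
  min(accuracy_cap, safety * dt_el, safety * dt_bend)
}

# Discrete flow rate (m^3/s) through the z-plane at face index k: the sum
# over the whole staggered plane, which the divergence-free projection makes
# identical for every k to rounding.
gate_flow <- function(state, sys, k) {
  sum(state$w[, , k]) * sys$grid$h_m^2
}

enforce_walls <- function(a, comp_entry, passes = 2) {
  a[!comp_entry$fluid] <- 0
  if (!is.null(comp_entry$reflect_quad)) {
    rhs <- as.vector(comp_entry$reflect_quad %*% as.vector(a))
    a[comp_entry$ghost_idx] <-
      as.vector(Matrix::solve(comp_entry$ghost_lu, rhs))
  }
  a
}

#' Advance the flow one time step
#'
#' Semi-implicit viscous step (spectral Helmholtz at the maximum viscosity
#' plus explicit variable-viscosity defect), IBM membrane forcing, ghost-node
#' wall enforcement, exact FFT pressure projection, and membrane advection
#' with the IBM kernel. After the projection the discrete divergence on every
#' cell is zero to rounding.
#'
#' @param state A `flow_state`.
#' @param sys A `flow_system`.
#' @param dt Time step, s.
#' @return The advanced `flow_state`.
#' @export
step_flow <- function(state, sys, dt) {
  g <- sys$grid
  h <- g$h_m
  rho <- sys$rho
  n <- g$n
  # refresh wall values on the current field before building the RHS
  state$u <- enforce_walls(state$u, g$comp$u)
  state$v <- enforce_walls(state$v, g$comp$v)
  state$w <- enforce_walls(state$w, g$comp$w)
  fx <- fy <- fz <- 0
  allv <- NULL
  kw_u <- kw_v <- kw_w <- NULL
  if (length(state$cells)) {
    pool <- pool_cells(state$cells)
    mf <- membrane_forces(pool, pool$vertices)
    state$max_strain <- mf$max_strain
    allv <- pool$vertices
    allF <- mf$force
    kw_u <- ibm_weights(allv, g, "u")
    kw_v <- ibm_weights(allv, g, "v")
    kw_w <- ibm_weights(allv, g, "w")
    fx <- ibm_spread(g, allv, allF[, 1], "u", kw_u, sys$cache, "spr_u")
    fy <- ibm_spread(g, allv, allF[, 2], "v", kw_v, sys$cache, "spr_v")
    fz <- ibm_spread(g, allv, allF[, 3], "w", kw_w, sys$cache, "spr_w")
    ve <- if (is.null(sys$visc_every)) 3L else sys$visc_every
    state$visc_age <- if (is.null(state$visc_age)) ve else state$visc_age + 1L
    if (state$visc_age >= ve) {
      vf <- viscosity_field(state$cells, g, sys$mu_plasma, sys$mu_interior,
                            cache = sys$cache)
      state$mu <- vf$mu
      state$indicator <- vf$indicator
      state$visc_age <- 0L
    }
  }
  mu0 <- sys$mu0
  vs <- if (length(state$cells)) {
    visc_divstress(state$u, state$v, state$w, state$mu, h)
  } else {
    list(x = sys$mu_plasma * laplacian(state$u, h),
         y = sys$mu_plasma * laplacian(state$v, h),
         z = sys$mu_plasma * laplacian(state$w, h))
  }
  dpx <- (state$p - pshift(state$p, -1, 1)) / h
  dpy <- (state$p - pshift(state$p, -1, 2)) / h
  dpz <- (state$p - pshift(state$p, -1, 3)) / h
  Gz <- state$G * g$comp$w$fluid
  ru <- dt / rho * (-dpx + vs$x + fx) * g$comp$u$fluid
  rv <- dt / rho * (-dpy + vs$y + fy) * g$comp$v$fluid
  rw <- dt / rho * (-dpz + vs$z + fz + Gz) * g$comp$w$fluid
  pre <- adi_cache(sys, dt)
  us <- state$u + adi_delta_solve(ru, pre$u)
  vsx <- state$v + adi_delta_solve(rv, pre$v)
  ws <- state$w + adi_delta_solve(rw, pre$w)
  dv <- divergence(us, vsx, ws, h)
  dp <- poisson_solve(rho / dt * dv, g)
  state$u <- us - dt / rho * (dp - pshift(dp, -1, 1)) / h
  state$v <- vsx - dt / rho * (dp - pshift(dp, -1, 2)) / h
  state$w <- ws - dt / rho * (dp - pshift(dp, -1, 3)) / h
  state$p <- state$p + dp
  if (length(state$cells)) {
    U <- cbind(ibm_interpolate(g, state$u, allv, "u", kw_u),
               ibm_interpolate(g, state$v, allv, "v", kw_v),
               ibm_interpolate(g, state$w, allv, "w", kw_w))
    z0 <- g$x0[3]; Lz <- sys$Lz
    i0 <- 1
    for (ci in seq_along(state$cells)) {
      nvtx <- nrow(state$cells[[ci]]$vertices)
      Xi <- state$cells[[ci]]$vertices + dt * U[i0:(i0 + nvtx - 1), ] / .UM
      cz <- mean(Xi[, 3])
      if (cz >= z0 + Lz) Xi[, 3] <- Xi[, 3] - Lz
      if (cz < z0) Xi[, 3] <- Xi[, 3] + Lz
      state$cells[[ci]]$vertices <- Xi
      i0 <- i0 + nvtx
    }
  }
  if (sys$bc$kind == "inlet_flow_rate") {
    k_gate <- which.max(apply(sys$grid$comp$w$fluid, 3, sum))
    Q <- gate_flow(state, sys, k_gate)
    if (Q > 0) {
      fac <- (sys$bc$value / Q)^0.7
      state$G <- state$G * min(max(fac, 0.5), 2)
    }
  }
  state$t <- state$t + dt
  state
}

#' Run a simulation to a time horizon
#'
#' Advances the coupled system, sampling every `cadence` seconds (default
#' 0.5 ms, the time-averaging cadence): monitors (flow rate, cell area and
#' volume drift), a running mean of the velocity field and of the cell
#' indicator, and any user `sample_fn(state, sys)` payload (e.g. an
#' instantaneous WSS field).
#'
#' @param sys A `flow_system`.
#' @param cells Optional list of placed cells.
#' @param horizon Physical time to simulate, s.
#' @param dt Time step, s; default from [stable_dt()].
#' @param cadence Sampling interval, s.
#' @param sample_fn Optional function of `(state, sys)` evaluated at every
#'   sample; results collected in `$samples`.
#' @param state Optional initial `flow_state` (to continue a run).
#' @param verbose Print progress.
#' @return A `sim_result`: final `state`, running `mean` fields, `monitors`
#'   tibble, `samples`, and bookkeeping.
#' @export
run_simulation <- function(sys, cells = list(), horizon, dt = NULL,
                           cadence = 5e-4, sample_fn = NULL, state = NULL,
                           verbose = FALSE) {
  if (is.null(state)) state <- flow_state(sys, cells)
  if (is.null(dt)) dt <- stable_dt(sys$grid, state$cells, sys$mu_plasma)
  nsteps <- ceiling(horizon / dt)
  every <- max(1L, round(cadence / dt))
  n <- sys$grid$n
  mu_sum <- list(u = array(0, n), v = array(0, n), w = array(0, n),
                 ind = array(0, n))
  nsamp <- 0
  ref_av <- lapply(state$cells, function(cl) area_volume(cl))
  monitors <- list()
  samples <- list()
  diverged <- FALSE
  k_gate <- which.max(apply(sys$grid$comp$w$fluid, 3, sum))
  for (s in seq_len(nsteps)) {
    # strain-adaptive substepping: the Skalak law stiffens with strain, so
    # highly strained membranes (junction apices, tight squeezes) are
    # advanced with proportionally smaller internal steps
    ms <- if (is.null(state$max_strain)) 0 else state$max_strain
    nsub <- if (ms > 3.5) 8L else if (ms > 2.2) 4L else if (ms > 1.2) 2L else 1L
    state_new <- tryCatch({
      stx <- state
      for (k in seq_len(nsub)) stx <- step_flow(stx, sys, dt / nsub)
      stx
    }, error = identity)
    if (inherits(state_new, "error") || !is.finite(sum(state_new$w))) {
      diverged <- TRUE
      warning(sprintf("run diverged at t = %.4g ms (last good state kept)%s",
                      state$t * 1e3,
                      if (inherits(state_new, "error"))
                        paste0(": ", conditionMessage(state_new)) else ""))
      break
    }
    state <- state_new
    if (s %% every == 0) {
      nsamp <- nsamp + 1
      mu_sum$u <- mu_sum$u + state$u
      mu_sum$v <- mu_sum$v + state$v
      mu_sum$w <- mu_sum$w + state$w
      if (!is.null(state$indicator)) mu_sum$ind <- mu_sum$ind + state$indicator
      drift <- c(area = NA_real_, volume = NA_real_)
      if (length(state$cells)) {
        av <- sapply(seq_along(state$cells), function(i)
          area_volume(state$cells[[i]]) / ref_av[[i]] - 1)
        drift <- c(area = max(abs(av[1, ])), volume = max(abs(av[2, ])))
      }
      monitors[[nsamp]] <- tibble::tibble(
        t = state$t, Q = gate_flow(state, sys, k_gate), G = state$G,
        area_drift = drift[["area"]], volume_drift = drift[["volume"]])
      if (!is.null(sample_fn)) samples[[nsamp]] <- sample_fn(state, sys)
      if (verbose) message(sprintf("t = %.4g ms, Q = %.3g", state$t * 1e3,
                                   monitors[[nsamp]]$Q))
    }
  }
  mean_fields <- lapply(mu_sum, function(a) a / max(nsamp, 1))
  structure(list(state = state, mean = mean_fields, sys = sys,
                 monitors = dplyr::bind_rows(monitors), samples = samples,
                 dt = dt, n_samples = nsamp, diverged = diverged),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> t = %.3g ms, %d samples, %d cells%s\n",
              x$state$t * 1e3, x$n_samples, length(x$state$cells),
              if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Run-level summary of a simulation
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return One-row tibble: horizon, flow rate, drifts, divergence flag.
#' @export
glance.sim_result <- function(x, ...) {
  m <- x$monitors
  tibble::tibble(
    t_final = x$state$t, n_samples = x$n_samples,
    n_cells = length(x$state$cells),
    Q_mean = mean(m$Q[max(1, nrow(m) %/% 2):nrow(m)]),
    area_drift = m$area_drift[nrow(m)],
    volume_drift = m$volume_drift[nrow(m)],
    diverged = x$diverged)
}
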