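# Wall shear stress and its surface gradient.
#
# The traction at each wall-mesh vertex is expressed in a local cylindrical
# frame: e_r along the inward wall normal, e_s along the local near-wall flow
# direction, e_theta completing the right-handed triad. The wall shear
# stress tau is the streamwise component t_s = mu * du_s/dr evaluated with a
# one-sided second-order stencil inside a 300 nm band (the cell-free layer,
# hence the plasma viscosity), and the WSS gradient is a second-order
# central difference along the surface with the same stencil span.

#' Time-average a series of velocity fields
#'
#' @param states List of `flow_state` objects (or lists with `u`, `v`, `w`
#'   arrays) sampled at uniform cadence.
#' @return List with mean `u`, `v`, `w` arrays and `n_samples`.
#' @export
time_average <- function(states) {
  stopifnot(length(states) >= 2)
  d0 <- dim(states[[1]]$u)
  out <- list(u = 0, v = 0, w = 0)
  for (s in states) {
    if (!identical(dim(s$u), d0)) stop("mismatched grids in time series")
    out$u <- out$u + s$u; out$v <- out$v + s$v; out$w <- out$w + s$w
  }
  n <- length(states)
  list(u = out$u / n, v = out$v / n, w = out$w / n, n_samples = n)
}

# nearest-centerline tangent for every mesh vertex (stagnation fallback)
centerline_tangents <- function(mesh) {
  spec <- mesh$spec
  if (is.null(spec)) return(matrix(rep(c(0, 0, 1), each = nrow(mesh$vertices)),
                                   ncol = 3))
  v <- mesh$vertices
  best_d <- rep(Inf, nrow(v))
  tans <- matrix(0, nrow(v), 3)
  for (vs in spec$vessels) {
    d <- abs(dist_to_polyline(v, vs$centerline) - vs$diameter / 2)
    upd <- d < best_d
    if (any(upd)) {
      p <- vs$centerline
      tt <- p[nrow(p), ] - p[1, ]
      tt <- tt / sqrt(sum(tt^2))
      tans[upd, ] <- matrix(tt, sum(upd), 3, byrow = TRUE)
      best_d[upd] <- d[upd]
    }
  }
  tans
}

#' Local flow-aligned frames at wall vertices
#'
#' Builds the per-vertex cylindrical frame: `e_r` is the inward wall normal;
#' `e_s` is the normalized tangential projection of the velocity interpolated
#' at a probe point one stencil span inside the wall (so it points along the
#' local near-wall flow); `e_theta = e_r x e_s`. Vertices where the probe
#' velocity nearly vanishes (stagnation, e.g. junction apices) fall back to
#' the parent vessel's centerline tangent and are flagged.
#'
#' @param mesh A `wall_mesh`.
#' @param fields List with `u`, `v`, `w` velocity arrays (m/s).
#' @param sys The `flow_system` that produced the fields.
#' @param probe_dist Distance of the direction probe inside the wall, um.
#' @param stagnation_rel Relative speed threshold below which a vertex is
#'   treated as stagnant.
#' @return A `local_frames` object: `e_r`, `e_s`, `e_theta` (n x 3) and
#'   logical `stagnant`.
#' @export
local_frames <- function(mesh, fields, sys, probe_dist = 0.3,
                         stagnation_rel = 1e-6) {
  n_in <- -mesh$normals
  probe <- mesh$vertices + probe_dist * n_in
  up <- interp_velocity(refill_fields(fields, sys$grid), sys$grid, probe)
  ut <- up - rowSums(up * n_in) * n_in
  sp <- sqrt(rowSums(ut^2))
  stag <- sp < stagnation_rel * max(sp)
  e_s <- ut / pmax(sp, 1e-300)
  if (any(stag)) {
    ct <- centerline_tangents(mesh)
    ctt <- ct - rowSums(ct * n_in) * n_in
    ctt <- ctt / pmax(sqrt(rowSums(ctt^2)), 1e-12)
    e_s[stag, ] <- ctt[stag, , drop = FALSE]
  }
  e_th <- vec_cross(n_in, e_s)
  e_th <- e_th / pmax(sqrt(rowSums(e_th^2)), 1e-12)
  structure(list(e_r = n_in, e_s = e_s, e_theta = e_th, stagnant = stag),
            class = "local_frames")
}

#' Wall traction components (WSS) at wall-mesh vertices
#'
#' Computes the traction components in the local frame from velocities
#' interpolated at probe points 0, span/2 and span along the inward normal
#' (the wall value is zero by no-slip), differentiated with the one-sided
#' second-order stencil `f'(0) = (4 f(d) - f(2d)) / (2d)`. The stencil span
#' stays below 300 nm so it lies within the cell-free layer, and the plasma
#' viscosity is used regardless of cell proximity. Components are reported
#' in dyne/cm^2 (1 Pa = 10 dyne/cm^2); `t_s` is the WSS tau.
#'
#' @param fields List with `u`, `v`, `w` (m/s), instantaneous or
#'   time-averaged; optionally `p` (Pa) for the wall pressure.
#' @param mesh A `wall_mesh`.
#' @param frames A `local_frames` from [local_frames()].
#' @param sys The `flow_system`.
#' @param stencil_span Total stencil extent, um (<= 0.3).
#' @param viscosity Viscosity used in the gradient, Pa s (plasma).
#' @param averaged Mark the result as time-averaged.
#' @param wall_value `"noslip"` (default) anchors the radial fit at
#'   `u(wall) = 0`; `"field"` takes the wall value from the field itself
#'   (unconstrained fit), so the stencil annihilates constant fields --
#'   useful for consistency checks on painted fields.
#' @return A `wss_field`: `t_s`, `t_theta`, `t_r_visc`, `p_wall`
#'   (dyne/cm^2), `valid`, the `frames`, and metadata.
#' @export
wall_shear_stress <- function(fields, mesh, frames, sys, stencil_span = 0.3,
                              viscosity = NULL, averaged = FALSE,
                              wall_value = c("noslip", "field")) {
  wall_value <- match.arg(wall_value)
  if (stencil_span > 0.3 + 1e-12)
    stop("stencil_span must be <= 0.3 um (cell-free layer)")
  if (is.null(viscosity)) viscosity <- sys$mu_plasma
  n_in <- frames$e_r
  nv <- nrow(mesh$vertices)
  phi <- if (!is.null(mesh$phi)) mesh$phi else sys$field$phi
  span <- rep(stencil_span, nv)
  # the deepest radial sample must stay inside the lumen; thin spots are
  # handled by shrinking the sampling depth once, then flagged invalid
  h_grid <- sys$grid$h
  depth_scale <- rep(1, nv)
  deep <- mesh$vertices + 2 * h_grid * n_in
  bad <- phi(deep) >= -0.1 * h_grid
  depth_scale[bad] <- 0.6
  deep <- mesh$vertices + 2 * h_grid * depth_scale * n_in
  valid <- phi(deep) < -0.1 * h_grid
  d1 <- span / 2
  if (wall_value == "noslip") fields <- refill_fields(fields, sys$grid)
  # Stencil-point velocities: the grid cannot resolve sub-cell distances
  # directly, so velocity at the stencil points is evaluated from a
  # no-slip-constrained quadratic radial profile u(r) = c1 r + c2 r^2
  # fitted per vertex to samples at depths (1, 1.5, 2) h along the inward
  # normal (all in well-resolved fluid).
  dep <- outer(depth_scale, c(1, 1.5, 2) * h_grid)   # nv x 3 depths, um
  smp <- lapply(1:3, function(j) {
    pj <- mesh$vertices + dep[, j] * n_in
    cbind(interp_component_quad(fields$u, sys$grid, pj, "u"),
          interp_component_quad(fields$v, sys$grid, pj, "v"),
          interp_component_quad(fields$w, sys$grid, pj, "w"))
  })
  dd <- d1 * .UM                       # m
  if (wall_value == "noslip") {
    # no-slip-anchored least-squares fit u(r) = c1 r + c2 r^2
    s11 <- rowSums(dep^2); s12 <- rowSums(dep^3); s22 <- rowSums(dep^4)
    det <- s11 * s22 - s12^2
    cfs <- lapply(1:3, function(k) {   # c1, c2 for Cartesian component k
      b1 <- dep[, 1] * smp[[1]][, k] + dep[, 2] * smp[[2]][, k] +
        dep[, 3] * smp[[3]][, k]
      b2 <- dep[, 1]^2 * smp[[1]][, k] + dep[, 2]^2 * smp[[2]][, k] +
        dep[, 3]^2 * smp[[3]][, k]
      cbind((s22 * b1 - s12 * b2) / det, (s11 * b2 - s12 * b1) / det)
    })
    u_at <- function(d) sapply(1:3, function(k)
      cfs[[k]][, 1] * d + cfs[[k]][, 2] * d^2)
    u1 <- u_at(d1)
    u2 <- u_at(span)
    ddu <- function(e) (4 * rowSums(u1 * e) - rowSums(u2 * e)) / (2 * dd)
  } else {
    # unconstrained quadratic through the three samples (Lagrange basis);
    # the wall value comes from the field, so constants differentiate to 0
    lagw <- function(x) {              # nv x 3 weights at radius x (vector)
      w <- matrix(0, nv, 3)
      for (i in 1:3) {
        o <- setdiff(1:3, i)
        w[, i] <- (x - dep[, o[1]]) / (dep[, i] - dep[, o[1]]) *
          (x - dep[, o[2]]) / (dep[, i] - dep[, o[2]])
      }
      w
    }
    u_at <- function(w) sapply(1:3, function(k)
      w[, 1] * smp[[1]][, k] + w[, 2] * smp[[2]][, k] + w[, 3] * smp[[3]][, k])
    u0 <- u_at(lagw(rep(0, nv)))
    u1 <- u_at(lagw(d1))
    u2 <- u_at(lagw(span))
    ddu <- function(e) (-3 * rowSums(u0 * e) + 4 * rowSums(u1 * e) -
                          rowSums(u2 * e)) / (2 * dd)
  }
  t_s <- viscosity * ddu(frames$e_s) * 10
  t_th <- viscosity * ddu(frames$e_theta) * 10
  t_rv <- 2 * viscosity * ddu(frames$e_r) * 10
  p_wall <- if (!is.null(fields$p))
    interp_component(fields$p, sys$grid, mesh$vertices + d1 * n_in, "c") * 10
  else rep(NA_real_, nv)
  structure(list(t_s = t_s, t_theta = t_th, t_r_visc = t_rv, p_wall = p_wall,
                 valid = valid, frames = frames, mesh = mesh,
                 averaged = averaged, span = span,
                 bc_kind = sys$bc$kind), class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field>%s %d vertices (%d valid), tau in [%.2f, %.2f] dyne/cm^2\n",
              if (x$averaged) " time-averaged" else "", length(x$t_s),
              sum(x$valid), min(x$t_s[x$valid]), max(x$t_s[x$valid])))
  invisible(x)
}

#' Per-vertex traction table
#' @param x A `wss_field`.
#' @param ... Unused.
#' @return Tibble with vertex id, ROI label, traction components and flags.
#' @export
tidy.wss_field <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$t_s), roi = x$mesh$roi,
                 tau = x$t_s, t_theta = x$t_theta, t_r_visc = x$t_r_visc,
                 valid = x$valid, stagnant = x$frames$stagnant)
}

# Grid-hash k-nearest-neighbour search among mesh vertices.
knn_surface <- function(verts, query, k, cell = NULL) {
  if (is.null(cell)) {
    bb <- apply(verts, 2, range)
    cell <- max(1e-6, (prod(bb[2, ] - bb[1, ] + 1e-9) / nrow(verts))^(1 / 3) * 2)
  }
  key <- function(p) paste(floor(p[, 1] / cell), floor(p[, 2] / cell),
                           floor(p[, 3] / cell))
  vk <- key(verts)
  buckets <- split(seq_len(nrow(verts)), vk)
  out <- matrix(NA_integer_, nrow(query), k)
  qf <- cbind(floor(query[, 1] / cell), floor(query[, 2] / cell),
              floor(query[, 3] / cell))
  for (i in seq_len(nrow(query))) {
    cand <- integer(0)
    r <- 1L
    repeat {
      keys <- as.vector(outer(
        as.vector(outer((qf[i, 1] - r):(qf[i, 1] + r),
                        (qf[i, 2] - r):(qf[i, 2] + r), paste)),
        (qf[i, 3] - r):(qf[i, 3] + r), paste))
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (length(cand) >= k || r > 6L) break
      r <- r + 1L
    }
    if (length(cand)) {
      d2 <- (verts[cand, 1] - query[i, 1])^2 +
        (verts[cand, 2] - query[i, 2])^2 + (verts[cand, 3] - query[i, 3])^2
      out[i, seq_len(min(k, length(cand)))] <-
        cand[order(d2)][seq_len(min(k, length(cand)))]
    }
  }
  out
}

# Moving-least-squares (local linear) interpolation of a vertex scalar at
# off-vertex surface points: fit tau = a + b.xi in the tangent plane of the
# parent vertex from the k nearest valid vertices; exact on linear fields.
mls_surface_interp <- function(pts, e1, e2, origin, verts, values, nbrs) {
  n <- nrow(pts)
  out <- numeric(n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    id <- nbrs[i, ]
    id <- id[!is.na(id)]
    if (length(id) < 3) { ok[i] <- FALSE; next }
    dp <- sweep(verts[id, , drop = FALSE], 2, origin[i, ])
    X <- cbind(1, dp %*% e1[i, ], dp %*% e2[i, ])
    fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, values[id])),
                    error = function(e) NULL)
    if (is.null(fit)) { ok[i] <- FALSE; next }
    dq <- pts[i, ] - origin[i, ]
    out[i] <- fit[1] + fit[2] * sum(dq * e1[i, ]) + fit[3] * sum(dq * e2[i, ])
  }
  list(value = out, ok = ok)
}

#' Surface gradient of the WSS (WSSG)
#'
#' Axial and circumferential WSS gradients by second-order central
#' differencing along the local frame directions: the stencil endpoints are
#' stepped a half-span along `e_s` (or `e_theta`), projected back onto the
#' wall surface, and tau is interpolated there by a local linear
#' (moving-least-squares) fit over the nearest valid vertices, with the
#' total stencil distance equal to the WSS stencil span.
#'
#' @param wss A `wss_field` (typically time-averaged).
#' @param mesh A `wall_mesh`.
#' @param frames `local_frames` used for the directions.
#' @param stencil_span Total stencil extent, um.
#' @param k_neighbors Vertices used in the local linear fit.
#' @param smooth_iters Optional MLS smoothing passes applied to tau before
#'   differencing (each pass replaces tau by its local linear fit, which
#'   reproduces linear fields exactly); reduces the grid-staircase noise
#'   floor on measured fields.
#' @return A `wssg_field`: `grad_s`, `grad_theta`, `grad_mag`
#'   (dyne/cm^2/um) and `valid`.
#' @export
wssg <- function(wss, mesh, frames, stencil_span = 0.3, k_neighbors = 8,
                 smooth_iters = 0) {
  delta <- stencil_span / 2
  v <- mesh$vertices
  nv <- nrow(v)
  if (smooth_iters > 0) {
    vu <- which(wss$valid)
    nb <- knn_surface(v[vu, , drop = FALSE], v, max(k_neighbors, 12))
    nbm <- matrix(vu[nb], nrow(nb))
    for (it in seq_len(smooth_iters)) {
      sm <- mls_surface_interp(v, frames$e_s, frames$e_theta, v, v,
                               wss$t_s, nbm)
      wss$t_s <- ifelse(sm$ok, sm$value, wss$t_s)
    }
  }
  phi <- mesh$phi
  proj <- function(p) {
    if (is.null(phi)) return(p)
    for (it in 1:2) {
      g <- sdf_gradient(phi, p, eps = 0.05)
      p <- p - phi(p) * g / pmax(rowSums(g^2), 1e-12)
    }
    p
  }
  vuse <- which(wss$valid)
  grads <- list()
  for (dir in c("e_s", "e_theta")) {
    pp <- proj(v + delta * frames[[dir]])
    pm <- proj(v - delta * frames[[dir]])
    nb_p <- knn_surface(v[vuse, , drop = FALSE], pp, k_neighbors)
    nb_m <- knn_surface(v[vuse, , drop = FALSE], pm, k_neighbors)
    remap <- function(nb) matrix(vuse[nb], nrow(nb))
    ip <- mls_surface_interp(pp, frames$e_s, frames$e_theta, v, v, wss$t_s,
                             remap(nb_p))
    im <- mls_surface_interp(pm, frames$e_s, frames$e_theta, v, v, wss$t_s,
                             remap(nb_m))
    grads[[dir]] <- list(g = (ip$value - im$value) / (2 * delta),
                         ok = ip$ok & im$ok)
  }
  valid <- wss$valid & grads$e_s$ok & grads$e_theta$ok
  gs <- grads$e_s$g; gt <- grads$e_theta$g
  structure(list(grad_s = gs, grad_theta = gt,
                 grad_mag = sqrt(gs^2 + gt^2), valid = valid,
                 mesh = mesh, averaged = wss$averaged,
                 bc_kind = wss$bc_kind), class = "wssg_field")
}

#' @export
print.wssg_field <- function(x, ...) {
  cat(sprintf("<wssg_field> |grad tau| up to %.2f dyne/cm^2/um (%d valid)\n",
              max(x$grad_mag[x$valid]), sum(x$valid)))
  invisible(x)
}
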