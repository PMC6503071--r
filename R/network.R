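# Synthetic microvessel network specifications and meshing.
#
# A `network_spec` holds vessels (id, centerline polyline in um, diameter in
# um, Strahler order, class) and junctions (kind, feeders, daughters). The
# morphometry follows in vivo microvascular ranges: diameters 6-24 um,
# lengths 25-165 um, three Strahler orders spanning the arterial and venous
# sides, with Horton's law linking diameters of consecutive orders.

#' Create a network specification
#'
#' @param vessels List of vessels, each a list with `id`, `centerline`
#'   (k x 3 matrix, um), `diameter` (um), `order` (1--3), `class`
#'   (`"arteriole"`, `"capillary"` or `"venule"`).
#' @param junctions List of junctions, each with `kind` (`"bifurcation"` or
#'   `"convergence"`), `feeders` (vessel ids), `daughters` (vessel ids) and
#'   `center` (position, um).
#' @param inlet,outlet Inlet and outlet vessel ids.
#' @param horton_ratio Diameter ratio between consecutive Strahler orders.
#' @param validate Check morphometric invariants (default `TRUE`).
#' @return A `network_spec`.
#' @export
network_spec <- function(vessels, junctions = list(), inlet = NULL,
                         outlet = NULL, horton_ratio = NA_real_,
                         validate = TRUE) {
  spec <- structure(list(vessels = vessels, junctions = junctions,
                         inlet = inlet, outlet = outlet,
                         horton_ratio = horton_ratio),
                    class = "network_spec")
  if (validate) validate_network_spec(spec)
  spec
}

validate_network_spec <- function(spec) {
  for (vs in spec$vessels) {
    if (vs$diameter < 6 || vs$diameter > 24)
      stop(sprintf("vessel %s diameter %.2f um outside [6, 24]",
                   vs$id, vs$diameter))
    len <- polyline_length(vs$centerline)
    if (len < 25 || len > 165)
      stop(sprintf("vessel %s length %.1f um outside [25, 165]", vs$id, len))
  }
  for (jn in spec$junctions) {
    if (jn$kind == "bifurcation" &&
        (length(jn$feeders) != 1 || length(jn$daughters) != 2))
      stop("bifurcation must have 1 feeder and 2 daughters")
    if (jn$kind == "convergence" &&
        (length(jn$feeders) != 2 || length(jn$daughters) != 1))
      stop("convergence must have 2 feeders and 1 collector")
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  kinds <- vapply(x$junctions, function(j) j$kind, "")
  cat(sprintf("<network_spec> %d vessels, %d bifurcations, %d convergences\n",
              length(x$vessels), sum(kinds == "bifurcation"),
              sum(kinds == "convergence")))
  invisible(x)
}

#' Vessel summary of a network specification
#' @param x A `network_spec`.
#' @param ... Unused.
#' @return A tibble with one row per vessel: id, diameter, length, order,
#'   class.
#' @export
tidy.network_spec <- function(x, ...) {
  tibble::tibble(
    id = vapply(x$vessels, function(v) v$id, 0),
    diameter = vapply(x$vessels, function(v) v$diameter, 0),
    length = vapply(x$vessels, function(v) polyline_length(v$centerline), 0),
    order = vapply(x$vessels, function(v) as.integer(v$order), 0L),
    class = vapply(x$vessels, function(v) v$class, ""))
}

# Mesh a network_spec by marching tetrahedra on the capsule-union SDF,
# optionally clipped by cap planes; labels vertices by ROI.
mesh_from_spec <- function(spec, mesh_size, caps = NULL,
                           junction_extent = 1, pad = 2,
                           open_caps = TRUE) {
  phi <- function(p) network_sdf(spec, p, caps = caps)
  allp <- do.call(rbind, lapply(spec$vessels, function(v) v$centerline))
  rmax <- max(vapply(spec$vessels, function(v) v$diameter, 0)) / 2
  bbox <- rbind(apply(allp, 2, min) - rmax - pad,
                apply(allp, 2, max) + rmax + pad)
  ax <- lapply(1:3, function(d) seq(bbox[1, d], bbox[2, d], by = mesh_size))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  vals <- array(phi(pts), dim = vapply(ax, length, 0L))
  mm <- marching_tetrahedra(vals, ax)
  mm <- orient_outward(mm, phi)
  v <- mm$vertices
  roi <- rep(NA_character_, nrow(v))
  # cap vertices: on a cap plane within half a cell
  on_cap <- rep(FALSE, nrow(v))
  if (!is.null(caps)) {
    for (cp in caps) {
      dd <- as.vector(sweep(v, 2, cp$point) %*% cp$normal)
      on_cap <- on_cap | abs(dd) < mesh_size / 4
    }
  }
  # nearest-vessel attribution for lateral vertices
  dmat <- sapply(spec$vessels, function(vs)
    dist_to_polyline(v, vs$centerline) - vs$diameter / 2)
  near <- max.col(-abs(dmat))
  ids <- vapply(spec$vessels, function(vs) vs$id, 0)
  roi <- paste0("vessel:", ids[near])
  # junction regions: within junction_extent * feeder diameter of the center
  for (jn in spec$junctions) {
    fd <- spec$vessels[[match(jn$feeders[1], ids)]]$diameter
    r <- junction_extent * fd
    dj <- sqrt(rowSums(sweep(v, 2, jn$center)^2))
    roi[dj < r] <- paste0(jn$kind, ":", jn$id)
  }
  roi[on_cap] <- "cap"
  if (open_caps && any(on_cap)) {
    tr <- mm$triangles
    drop <- on_cap[tr[, 1]] & on_cap[tr[, 2]] & on_cap[tr[, 3]]
    tr <- tr[!drop, , drop = FALSE]
    keep <- sort(unique(as.vector(tr)))
    remap <- integer(nrow(v)); remap[keep] <- seq_along(keep)
    mm$triangles <- matrix(remap[tr], ncol = 3)
    v <- v[keep, , drop = FALSE]
    roi <- roi[keep]
  } else {
    mm$triangles <- mm$triangles
  }
  g <- sdf_gradient(phi, v)
  g <- g / pmax(sqrt(rowSums(g^2)), 1e-12)
  m <- new_wall_mesh(v, mm$triangles, g, roi, spec)
  m$phi <- phi
  m
}

#' Generate a single junction geometry (bifurcation or convergence)
#'
#' Builds a Y-shaped watertight surface with three open caps: one feeder
#' splitting into two daughters (bifurcation) or two feeders merging into a
#' collector (convergence). Vessels are swept straight segments meeting at
#' the origin; the surface comes from the capsule-union signed distance.
#'
#' @param kind `"bifurcation"` or `"convergence"`.
#' @param feeder_diameter Feeder (or collector) diameter, um.
#' @param branch_diameters Length-2 numeric, daughter/feeder branch
#'   diameters, um.
#' @param angles Length-2 numeric, branch angles from the trunk axis,
#'   degrees.
#' @param length Branch length, um.
#' @param mesh_size Marching-grid cell size, um.
#' @param junction_extent Junction ROI radius in feeder diameters.
#' @return A `wall_mesh` with ROI labels (junction region plus three vessel
#'   regions, caps removed) and attached `network_spec`.
#' @export
make_junction <- function(kind = c("bifurcation", "convergence"),
                          feeder_diameter, branch_diameters, angles,
                          length = 25, mesh_size = feeder_diameter / 10,
                          junction_extent = 1) {
  kind <- match.arg(kind)
  th <- angles * pi / 180
  L <- length
  trunk <- rbind(c(0, 0, -L), c(0, 0, 0))
  br1 <- rbind(c(0, 0, 0), c(sin(th[1]), 0, cos(th[1])) * L)
  br2 <- rbind(c(0, 0, 0), c(-sin(th[2]), 0, cos(th[2])) * L)
  vessels <- list(
    list(id = 1, centerline = trunk, diameter = feeder_diameter,
         order = 2L, class = if (kind == "bifurcation") "arteriole" else "venule"),
    list(id = 2, centerline = br1, diameter = branch_diameters[1],
         order = 1L, class = "capillary"),
    list(id = 3, centerline = br2, diameter = branch_diameters[2],
         order = 1L, class = "capillary"))
  jn <- list(list(id = 1, kind = kind,
                  feeders = if (kind == "bifurcation") 1 else c(2, 3),
                  daughters = if (kind == "bifurcation") c(2, 3) else 1,
                  center = c(0, 0, 0)))
  spec <- network_spec(vessels, jn, inlet = 1, outlet = c(2, 3),
                       validate = FALSE)
  caps <- list(
    list(point = trunk[1, ], normal = c(0, 0, -1)),
    list(point = br1[2, ], normal = br1[2, ] / sqrt(sum(br1[2, ]^2))),
    list(point = br2[2, ], normal = br2[2, ] / sqrt(sum(br2[2, ]^2))))
  # keep cap planes slightly inside the sampled box so the surface closes
  m <- mesh_from_spec(spec, mesh_size, caps = caps,
                      junction_extent = junction_extent)
  sm <- check_watertight(m)
  if (sm$n_nonmanifold_edges > 0)
    stop("junction surface self-intersects at these angles; reduce angles")
  m
}

# Sinusoidal lateral perturbation used for tortuous centerlines.
tortuous_centerline <- function(p0, p1, amplitude, n = 24, phase = 0,
                                periods = 1) {
  t <- seq(0, 1, length.out = n)
  base <- outer(1 - t, p0) + outer(t, p1)
  axis <- (p1 - p0) / sqrt(sum((p1 - p0)^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- ref - sum(ref * axis) * axis
  n1 <- n1 / sqrt(sum(n1^2))
  base + outer(amplitude * sin(periods * 2 * pi * t + phase), n1)
}

#' Generate a small Strahler-ordered microvascular network
#'
#' Builds an arterial tree descending over `n_orders` Strahler orders to the
#' capillary level, mirrored by a venous tree ascending back, so every
#' bifurcation is matched by a convergence. Diameters follow Horton's law
#' (ratio `horton_ratio` between consecutive orders, venous side slightly
#' wider); centerlines get a sinusoidal tortuosity perturbation with
#' amplitude `tortuosity * diameter`. All randomness (lengths, phases,
#' lateral spread) is governed by `seed`.
#'
#' @param n_orders Number of Strahler orders on each side (2 or 3).
#' @param horton_ratio Diameter ratio between consecutive orders.
#' @param tortuosity Amplitude of the centerline perturbation in units of the
#'   local diameter.
#' @param seed Integer seed fixing all random choices.
#' @param capillary_diameter Diameter of the order-1 vessels, um.
#' @param mesh If `TRUE` also mesh the wall surface (marching tetrahedra).
#' @param mesh_size Marching-grid cell size, um.
#' @return A `network_spec`, with the `wall_mesh` in attribute `mesh` when
#'   `mesh = TRUE`.
#' @export
build_network <- function(n_orders = 3, horton_ratio = 1.6, tortuosity = 0.3,
                          seed = 1, capillary_diameter = 7, mesh = FALSE,
                          mesh_size = capillary_diameter / 8) {
  stopifnot(n_orders %in% c(2, 3))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  d_order <- capillary_diameter * horton_ratio^(0:(n_orders - 1))
  if (any(d_order < 6) || any(d_order * 1.15 > 24))
    stop("diameter bounds [6, 24] um violated by this order/ratio combination")
  vessels <- list(); junctions <- list()
  vid <- 0; jid <- 0
  add_vessel <- function(p0, p1, diameter, order, class) {
    vid <<- vid + 1
    amp <- tortuosity * diameter
    cl <- tortuous_centerline(p0, p1, amp, phase = runif(1, 0, 2 * pi))
    vessels[[vid]] <<- list(id = vid, centerline = cl, diameter = diameter,
                            order = as.integer(order), class = class)
    vid
  }
  # arterial tree: 2^(n_orders - k) vessels of order k at depth level
  Lseg <- runif(2 * n_orders, 30, 45)     # per-level vessel length
  spread <- 28                             # lateral half-spread at capillary level
  z <- 0
  # tips: x-positions of the current open ends
  ends <- list(list(x = 0, id = NA))
  level_ids <- list()
  for (lev in seq_len(n_orders)) {
    ord <- n_orders - lev + 1
    cls <- if (ord == 1) "capillary" else "arteriole"
    n_here <- 2^(lev - 1)
    xs <- if (n_here == 1) 0 else seq(-spread, spread, length.out = n_here)
    z2 <- z + Lseg[lev]
    new_ids <- integer(n_here)
    for (i in seq_len(n_here)) {
      x_par <- if (lev == 1) 0 else parent_x[ceiling(i / 2)]
      new_ids[i] <- add_vessel(c(x_par, 0, z), c(xs[i], 0, z2),
                               d_order[ord], ord, cls)
    }
    if (lev > 1) {
      for (p in seq_len(n_here / 2)) {
        jid <- jid + 1
        junctions[[jid]] <- list(
          id = jid, kind = "bifurcation", feeders = parent_ids[p],
          daughters = new_ids[c(2 * p - 1, 2 * p)],
          center = c(parent_x[p], 0, z))
      }
    }
    parent_ids <- new_ids; parent_x <- xs
    z <- z2
  }
  # venous tree: mirror, ascending orders, slightly wider vessels
  for (lev in seq_len(n_orders - 1)) {
    ord <- lev + 1
    cls <- if (ord == n_orders) "venule" else "venule"
    n_here <- 2^(n_orders - lev - 1)
    xs <- if (n_here == 1) 0 else seq(-spread / 2, spread / 2, length.out = n_here)
    z2 <- z + Lseg[n_orders + lev]
    new_ids <- integer(n_here)
    for (i in seq_len(n_here)) {
      new_ids[i] <- add_vessel(c(parent_x[2 * i - 1] / 2 + xs[i] / 2, 0, z),
                               c(xs[i], 0, z2),
                               d_order[ord] * 1.15, ord, cls)
      jid <- jid + 1
      junctions[[jid]] <- list(
        id = jid, kind = "convergence",
        feeders = parent_ids[c(2 * i - 1, 2 * i)],
        daughters = new_ids[i],
        center = c(parent_x[2 * i - 1] / 2 + xs[i] / 2, 0, z))
    }
    # stitch feeder ends to the junction center
    for (i in seq_len(n_here)) {
      for (f in junctions[[jid - n_here + i]]$feeders) {
        cl <- vessels[[f]]$centerline
        cl[nrow(cl), ] <- junctions[[jid - n_here + i]]$center
        vessels[[f]]$centerline <- cl
      }
    }
    parent_ids <- new_ids; parent_x <- xs
    z <- z2
  }
  spec <- network_spec(vessels, junctions,
                       inlet = 1, outlet = parent_ids,
                       horton_ratio = horton_ratio)
  if (mesh) attr(spec, "mesh") <- mesh_from_spec(spec, mesh_size)
  spec
}

#' Periodic bifurcation--convergence loop fixture
#'
#' A feeder vessel splits into two parallel branches that merge back into the
#' feeder, laid out along z so the geometry is periodic in the axial
#' direction. This is the desk-scale flow fixture for junction statistics:
#' the spectral solver applies directly and cells recirculate naturally.
#'
#' @param feeder_diameter Feeder diameter, um.
#' @param branch_diameters Length-2 numeric, branch diameters, um.
#' @param branch_sep Lateral center-to-center separation of the branches, um.
#' @param feeder_len,branch_len Axial extents of the feeder sections and the
#'   branch section, um.
#' @param mesh_size Marching-grid cell size for the wall mesh, um.
#' @return A `wall_mesh` (attached `network_spec` and SDF closure `phi`);
#'   attribute `period` is the axial period, `gates` holds gate-plane
#'   stations for flux measurement.
#' @export
make_junction_loop <- function(feeder_diameter = 10,
                               branch_diameters = c(7, 5.5),
                               branch_sep = 14, feeder_len = 24,
                               branch_len = 28,
                               mesh_size = min(branch_diameters) / 8) {
  Lz <- feeder_len + branch_len
  half <- feeder_len / 2
  x1 <- branch_sep / 2; x2 <- -branch_sep / 2
  # periodic box spans z in [-half, -half + Lz]; both box ends sit in the
  # plain feeder cross-section so the wrap is geometrically exact
  taper <- 4
  zm <- half + branch_len                     # merge completes here
  feeder_lo <- rbind(c(0, 0, -half - 2), c(0, 0, half))
  br1 <- rbind(c(0, 0, half - 1), c(x1, 0, half + taper),
               c(x1, 0, zm - taper), c(0, 0, zm))
  br2 <- rbind(c(0, 0, half - 1), c(x2, 0, half + taper),
               c(x2, 0, zm - taper), c(0, 0, zm))
  feeder_hi <- rbind(c(0, 0, zm - 1), c(0, 0, zm + half + 2))
  vessels <- list(
    list(id = 1, centerline = feeder_lo, diameter = feeder_diameter,
         order = 2L, class = "arteriole"),
    list(id = 2, centerline = br1, diameter = branch_diameters[1],
         order = 1L, class = "capillary"),
    list(id = 3, centerline = br2, diameter = branch_diameters[2],
         order = 1L, class = "capillary"),
    list(id = 4, centerline = feeder_hi, diameter = feeder_diameter,
         order = 2L, class = "venule"))
  junctions <- list(
    list(id = 1, kind = "bifurcation", feeders = 1, daughters = c(2, 3),
         center = c(0, 0, half)),
    list(id = 2, kind = "convergence", feeders = c(2, 3), daughters = 4,
         center = c(0, 0, half + branch_len)))
  spec <- network_spec(vessels, junctions, inlet = 1, outlet = 4,
                       horton_ratio = NA_real_, validate = FALSE)
  m <- mesh_from_spec(spec, mesh_size, junction_extent = 0.8)
  # trim the wall mesh to the periodic box (vertices outside it describe
  # the overhang extensions, not the periodic geometry)
  zlo <- -half + 0.5; zhi <- -half + Lz - 0.5
  keep <- which(m$vertices[, 3] >= zlo & m$vertices[, 3] <= zhi)
  remap <- integer(nrow(m$vertices)); remap[keep] <- seq_along(keep)
  tr <- m$triangles
  tr <- tr[rowSums(matrix(m$vertices[tr, 3] >= zlo &
                            m$vertices[tr, 3] <= zhi, nrow(tr))) == 3, ,
           drop = FALSE]
  m2 <- new_wall_mesh(m$vertices[keep, , drop = FALSE],
                      matrix(remap[tr], ncol = 3),
                      m$normals[keep, , drop = FALSE], m$roi[keep], spec)
  m2$phi <- m$phi
  m <- m2
  attr(m, "period") <- Lz
  attr(m, "z_range") <- c(-half, -half + Lz)
  attr(m, "gates") <- list(
    feeder = list(point = c(0, 0, 0), normal = c(0, 0, 1),
                  radius = feeder_diameter / 2 + 1, vessel = 1,
                  full_plane = TRUE),
    branch1 = list(point = c(x1, 0, half + branch_len / 2), normal = c(0, 0, 1),
                   radius = branch_diameters[1] / 2 + 1, vessel = 2,
                   xside = 1, xsplit = 0),
    branch2 = list(point = c(x2, 0, half + branch_len / 2), normal = c(0, 0, 1),
                   radius = branch_diameters[2] / 2 + 1, vessel = 3,
                   xside = -1, xsplit = 0))
  m
}
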