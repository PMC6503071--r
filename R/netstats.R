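# Network-level statistics: flow and cell-flux partitioning at junctions,
# phase separation, per-vessel summary tables.

#' Flow and RBC-flux partitioning at a bifurcation
#'
#' Measures, over a run's sampled history, the time-averaged volumetric flow
#' rate through gate planes placed mid-vessel in the feeder and both
#' daughters, and the RBC flux as the rate of cell-centroid crossings of the
#' same gates. Returns the flow ratios `Q1* = Q_D1 / Q_F`,
#' `N1* = N_D1 / N_F` (and branch-2 analogues), the convention being that
#' branch 1 is the higher-`Q*` branch.
#'
#' @param result A `sim_result` from a junction-loop run whose `sample_fn`
#'   recorded `gate_flows` and `cell_z` payloads (see
#'   [gate_sample_fn()]), or equivalently a list with `samples`.
#' @param gates Gate definitions (from the geometry's `gates` attribute):
#'   each a list with `point`, `normal`, `radius`, `vessel`.
#' @param transient_frac Initial fraction of the sampled window excluded
#'   from averaging.
#' @return A one-row tibble (`bifurcation_flux`): Q and N per gate, starred
#'   ratios, and the phase-separation measure `N1* - Q1*`.
#' @export
branch_fluxes <- function(result, gates = NULL, transient_frac = 0.2) {
  if (is.null(gates)) gates <- attr(result$sys$mesh, "gates")
  if (is.null(gates)) stop("no gate definitions available")
  samp <- result$samples
  if (length(samp) < 5) stop("too few gate samples for flux averaging")
  n <- length(samp)
  use <- samp[(floor(transient_frac * n) + 1):n]
  Q <- colMeans(do.call(rbind, lapply(use, function(s) s$gate_flows)))
  # cell crossings: count sign changes of (z_cell - z_gate) between samples,
  # attributed to the gate whose lateral disc contains the crossing point
  nm <- names(gates)
  crossings <- setNames(numeric(length(gates)), nm)
  if (!is.null(use[[1]]$cell_pos) && nrow(use[[1]]$cell_pos) > 0) {
    for (i in 2:length(use)) {
      p0 <- use[[i - 1]]$cell_pos
      p1 <- use[[i]]$cell_pos
      for (gi in seq_along(gates)) {
        zg <- gates[[gi]]$point[3]
        cross <- (p0[, 3] - zg) < 0 & (p1[, 3] - zg) >= 0 &
          abs(p1[, 3] - p0[, 3]) < 10   # ignore periodic wrap jumps
        if (any(cross)) {
          mid <- (p0[cross, , drop = FALSE] + p1[cross, , drop = FALSE]) / 2
          r2 <- (mid[, 1] - gates[[gi]]$point[1])^2 +
            (mid[, 2] - gates[[gi]]$point[2])^2
          crossings[gi] <- crossings[gi] + sum(r2 < gates[[gi]]$radius^2)
        }
      }
    }
  }
  window <- use[[length(use)]]$t - use[[1]]$t
  N <- crossings / window
  qf <- Q[["feeder"]]; q1 <- Q[["branch1"]]; q2 <- Q[["branch2"]]
  nf <- N[["feeder"]]; n1 <- N[["branch1"]]; n2 <- N[["branch2"]]
  # branch 1 = higher-Q* branch (sign convention for phase separation)
  if (q2 > q1) { tmp <- q1; q1 <- q2; q2 <- tmp; tmp <- n1; n1 <- n2; n2 <- tmp }
  Q1s <- q1 / qf; Q2s <- q2 / qf
  N1s <- if (nf > 0) n1 / nf else NA_real_
  N2s <- if (nf > 0) n2 / nf else NA_real_
  tibble::tibble(Q_F = qf, Q_D1 = q1, Q_D2 = q2,
                 N_F = nf, N_D1 = n1, N_D2 = n2,
                 Q1_star = Q1s, Q2_star = Q2s,
                 N1_star = N1s, N2_star = N2s,
                 phase_sep = N1s - Q1s,
                 window = window)
}

#' Gate sampling callback for junction runs
#'
#' Builds a `sample_fn` for [run_simulation()] recording, at every cadence,
#' the instantaneous flow through each gate and all cell centroid positions,
#' which [branch_fluxes()] turns into Q* and N* ratios. For the axial
#' (z-normal) gates the generators emit, the flow is the exact discrete face
#' flux: the sum of the axial velocity over every staggered face inside the
#' gate disc (including the ghost ring, so the measure telescopes with the
#' solver's divergence-free constraint and is conserved to rounding).
#'
#' @param gates Gate definitions (geometry `gates` attribute).
#' @param margin Extra disc radius capturing the wall ghost ring, in grid
#'   cells.
#' @return A function `(state, sys) -> list(t, gate_flows, cell_pos)`.
#' @export
gate_sample_fn <- function(gates, margin = 2) {
  masks <- NULL
  function(state, sys) {
    g <- sys$grid
    if (is.null(masks)) {
      zax <- g$comp$w$axes[[3]]
      masks <<- lapply(gates, function(gt) {
        k <- which.min(abs(zax - gt$point[3]))
        xc <- g$comp$w$axes[[1]]; yc <- g$comp$w$axes[[2]]
        if (isTRUE(gt$full_plane)) {
          sel <- matrix(TRUE, g$n[1], g$n[2])
        } else if (!is.null(gt$xside)) {
          # half-plane attribution (junction branch planes): telescopes
          # exactly against the feeder full-plane flux
          xsplit <- if (is.null(gt$xsplit)) 0 else gt$xsplit
          side <- if (gt$xside > 0) xc > xsplit else xc <= xsplit
          sel <- outer(side, rep(TRUE, g$n[2]), `&`)
        } else {
          r2 <- outer((xc - gt$point[1])^2, (yc - gt$point[2])^2, `+`)
          sel <- r2 < (gt$radius + margin * g$h)^2
        }
        list(k = k, sel = sel)
      })
    }
    gf <- vapply(masks, function(m) sum(state$w[, , m$k][m$sel]) * g$h_m^2, 0)
    cp <- if (length(state$cells))
      do.call(rbind, lapply(state$cells, function(cl) colMeans(cl$vertices)))
    else matrix(0, 0, 3)
    list(t = state$t, gate_flows = gf, cell_pos = cp)
  }
}

#' Admissible tracer start positions in a lumen
#'
#' Samples centroid positions where a whole resting cell fits (every
#' template vertex clears the wall), without pairwise exclusion — the
#' excluded-volume distribution used by the finite-size tracer flux
#' estimator.
#'
#' @param field A sampled `distance_field`.
#' @param n Number of positions.
#' @param template A `cell_membrane` defining the excluded volume.
#' @param seed Integer seed.
#' @param clearance Wall clearance, um.
#' @return n x 3 matrix of centroid positions (um).
#' @export
seed_tracer_starts <- function(field, n, template = NULL, seed = 1,
                               clearance = 0.2) {
  if (is.null(template)) template <- make_biconcave(n_refine = 2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  deep <- which(field$values < -1)
  grid_pts <- as.matrix(expand.grid(field$axes[[1]], field$axes[[2]],
                                    field$axes[[3]]))[deep, , drop = FALSE]
  out <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(out) < n && tries < 200 * n) {
    tries <- tries + 1
    ctr <- grid_pts[sample(nrow(grid_pts), 1), ] +
      runif(3, -field$h / 2, field$h / 2)
    vv <- template$vertices %*% t(random_rotation(pi / 5)) +
      matrix(ctr, nrow(template$vertices), 3, byrow = TRUE)
    if (max(field$phi(vv)) < -clearance) out <- rbind(out, ctr)
  }
  out
}

#' Finite-size tracer flux partitioning in a frozen flow
#'
#' Advects cell-centroid tracers (seeded from the excluded-volume
#' distribution of whole resting cells, which concentrates them toward the
#' vessel axis like a flowing RBC core) through a frozen steady velocity
#' field and measures gate-crossing fluxes. Because the near-axis
#' streamlines preferentially enter the higher-flow daughter branch, the
#' resulting `N1* - Q1*` expresses the classical plasma-skimming
#' partitioning at a fraction of the cost of a coupled cell run.
#'
#' @param sys A `flow_system`.
#' @param state A (steady) `flow_state` whose velocity field is frozen.
#' @param gates Gate definitions (geometry `gates` attribute).
#' @param starts Tracer start positions from [seed_tracer_starts()].
#' @param horizon Advection time, s.
#' @param dt Advection step (RK2), s.
#' @return A `bifurcation_flux` tibble from [branch_fluxes()].
#' @export
tracer_fluxes <- function(sys, state, gates, starts, horizon = 0.04,
                          dt = 1e-4) {
  sf <- gate_sample_fn(gates)
  gf <- sf(state, sys)$gate_flows
  z0 <- sys$grid$x0[3]
  pos <- starts
  nsteps <- ceiling(horizon / dt)
  samples <- vector("list", nsteps)
  for (k in seq_len(nsteps)) {
    u1 <- interp_velocity(state, sys$grid, pos)
    mid <- pos + (dt / 2) * u1 / .UM
    mid[, 3] <- z0 + ((mid[, 3] - z0) %% sys$Lz)
    u2 <- interp_velocity(state, sys$grid, mid)
    pos <- pos + dt * u2 / .UM
    pos[, 3] <- z0 + ((pos[, 3] - z0) %% sys$Lz)
    samples[[k]] <- list(t = k * dt, gate_flows = gf, cell_pos = pos)
  }
  branch_fluxes(list(samples = samples, sys = sys), gates,
                transient_frac = 0)
}

#' Phase separation versus daughter-vessel WSS discrepancy
#'
#' Ordinary least-squares regression of the phase-separation measure
#' `N1* - Q1*` against the WSS discrepancy between daughter vessels
#' `tau_bar_D1 - tau_bar_D2`, across bifurcations (branch 1 is the
#' higher-`Q*` branch).
#'
#' @param data A tibble with columns `phase_sep` and `dtau` (one row per
#'   bifurcation), e.g. assembled from [branch_fluxes()] rows joined with
#'   ROI averages of the daughters.
#' @return A `psep_fit`: the `lm` fit plus the input data.
#' @export
phase_separation_vs_wss <- function(data) {
  stopifnot(all(c("phase_sep", "dtau") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 bifurcations")
  if (stats::var(data$dtau) == 0) {
    out <- list(fit = NULL, data = data, degenerate = TRUE)
    class(out) <- "psep_fit"
    return(out)
  }
  fit <- stats::lm(phase_sep ~ dtau, data = data)
  structure(list(fit = fit, data = data, degenerate = FALSE),
            class = "psep_fit")
}

#' @export
print.psep_fit <- function(x, ...) {
  if (x$degenerate) cat("<psep_fit> degenerate (zero x-variance)\n")
  else cat(sprintf("<psep_fit> slope %.4g, intercept %.4g, r = %.3f (n = %d)\n",
                   stats::coef(x$fit)[2], stats::coef(x$fit)[1],
                   sqrt(summary(x$fit)$r.squared) *
                     sign(stats::coef(x$fit)[2]),
                   nrow(x$data)))
  invisible(x)
}

#' @export
tidy.psep_fit <- function(x, ...) {
  if (x$degenerate)
    return(tibble::tibble(term = c("(Intercept)", "dtau"),
                          estimate = c(NA_real_, NA_real_),
                          std.error = c(NA_real_, NA_real_)))
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2])
}

#' @export
glance.psep_fit <- function(x, ...) {
  if (x$degenerate)
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, n = nrow(x$data), degenerate = TRUE))
  co <- stats::coef(x$fit)
  r <- suppressWarnings(stats::cor(x$data$dtau, x$data$phase_sep))
  tibble::tibble(slope = unname(co[2]), intercept = unname(co[1]),
                 r = r, n = nrow(x$data), degenerate = FALSE)
}

#' Per-vessel summary table from a paired run
#'
#' One row per vessel of the network: diameter, class, ROI-averaged WSS with
#' and without cells, their ratio, normalized standard deviations, and (when
#' gradients are supplied) WSSG magnitudes.
#'
#' @param wss_rbc,wss_pl Time-averaged `wss_field`s from the paired runs
#'   (plasma member may be `NULL` for an unpaired table).
#' @param mesh The shared `wall_mesh`.
#' @param wssg_rbc,wssg_pl Optional `wssg_field`s.
#' @return A tibble, one row per vessel ROI.
#' @export
vessel_table <- function(wss_rbc, wss_pl = NULL, mesh,
                         wssg_rbc = NULL, wssg_pl = NULL) {
  spec <- mesh$spec
  vt <- tidy.network_spec(spec)
  rows <- lapply(seq_len(nrow(vt)), function(i) {
    r <- paste0("vessel:", vt$id[i])
    if (!any(mesh$roi == r)) return(NULL)
    out <- tibble::tibble(
      id = vt$id[i], diameter = vt$diameter[i], class = vt$class[i],
      tau_rbc = roi_average(wss_rbc, mesh, r),
      tau_std_rbc = tryCatch(vessel_std(wss_rbc, mesh, r),
                             error = function(e) NA_real_))
    if (!is.null(wss_pl)) {
      out$tau_pl <- roi_average(wss_pl, mesh, r)
      out$tau_std_pl <- tryCatch(vessel_std(wss_pl, mesh, r),
                                 error = function(e) NA_real_)
      out$ratio <- out$tau_rbc / out$tau_pl
    }
    if (!is.null(wssg_rbc)) out$gmag_rbc <- roi_average(wssg_rbc, mesh, r)
    if (!is.null(wssg_pl)) out$gmag_pl <- roi_average(wssg_pl, mesh, r)
    out
  })
  dplyr::bind_rows(rows)
}
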