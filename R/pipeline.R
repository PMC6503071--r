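# Run orchestration: reproducible configurations, paired RBC/plasma runs,
# and the analytic fixture suite.

#' Assemble a run configuration
#'
#' Bundles everything a reproducible run needs: geometry, boundary
#' condition, seeding, solver resolution and horizon, sampling cadence and
#' pipeline options. A content hash of the resolved configuration is
#' attached so outputs can be traced to it.
#'
#' @param geometry A `wall_mesh` fixture (tube, loop, network).
#' @param bc List with `kind` (`"pressure_drop"` Pa/um or
#'   `"inlet_flow_rate"` m^3/s) and `value`.
#' @param hematocrit Feed hematocrit for the cell-laden member.
#' @param seed Integer seed for all randomness.
#' @param h Grid spacing, um.
#' @param horizon Physical time, s.
#' @param cadence Sampling interval, s (0.5 ms default).
#' @param stencil_span WSS stencil span, um.
#' @param dt Time step, s (`NULL`: from [stable_dt()]).
#' @param n_refine Cell mesh refinement level.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(geometry, bc, hematocrit = 0.3, seed = 1, h = 0.5,
                       horizon = 0.02, cadence = 5e-4, stencil_span = 0.3,
                       dt = NULL, n_refine = 3) {
  cfg <- list(geometry = geometry, bc = bc, hematocrit = hematocrit,
              seed = seed, h = h, horizon = horizon, cadence = cadence,
              stencil_span = stencil_span, dt = dt, n_refine = n_refine)
  if (!is.null(dt) && abs(cadence / dt - round(cadence / dt)) > 1e-9)
    stop("cadence must be an integer multiple of dt")
  tf <- tempfile()
  saveRDS(cfg[setdiff(names(cfg), "geometry")], tf)
  cfg$hash <- unname(tools::md5sum(tf))
  unlink(tf)
  class(cfg) <- "run_config"
  cfg
}

# run one member (plasma or cells) of a pair and compute its averaged WSS
run_member <- function(cfg, sys, cells, sample_fn = NULL) {
  dt <- cfg$dt
  if (is.null(dt)) dt <- stable_dt(sys$grid, cells, sys$mu_plasma)
  res <- run_simulation(sys, cells = cells, horizon = cfg$horizon, dt = dt,
                        cadence = cfg$cadence, sample_fn = sample_fn)
  fields <- res$mean
  fr <- local_frames(cfg$geometry, fields, sys)
  ws <- wall_shear_stress(fields, cfg$geometry, fr, sys,
                          stencil_span = cfg$stencil_span, averaged = TRUE)
  list(result = res, frames = fr, wss = ws, fields = fields)
}

#' Paired cell-laden and plasma-only runs
#'
#' Runs the same geometry twice under identical boundary conditions, once
#' with red cells seeded at the configured hematocrit and once with pure
#' plasma, computes the time-averaged WSS for both, and joins them into the
#' RBC-influence ratio report. Ratio-bearing pairs must use the
#' inlet-flow-rate boundary condition; a pressure pair is allowed but its
#' ratio report is refused.
#'
#' @param cfg A `run_config`.
#' @param plasma_first If the BC is `inlet_flow_rate` given as
#'   `value = NULL`, the plasma member runs first under the configured
#'   pressure drop and its steady flow rate becomes the target for both.
#' @return A `run_pair` list: `rbc`, `plasma` (each with `result`, `wss`,
#'   `fields`, `frames`), `ratio` (tibble or `NULL` for pressure pairs),
#'   `config`.
#' @export
run_pair <- function(cfg, plasma_first = TRUE) {
  geom <- cfg$geometry
  sys <- flow_system(geom, h = cfg$h, bc = cfg$bc)
  field <- sys$field
  sdf <- signed_distance(geom, h = min(cfg$h,
                                       min(vapply(geom$spec$vessels,
                                                  function(v) v$diameter, 0)) / 8),
                         bbox = field$bbox)
  cells <- if (cfg$hematocrit > 0)
    seed_cells(sdf, cfg$hematocrit, seed = cfg$seed,
               cell_template = make_biconcave(n_refine = cfg$n_refine))
  else list()
  pl <- run_member(cfg, sys, list())
  rb <- run_member(cfg, sys, cells)
  ratio <- NULL
  if (identical(cfg$bc$kind, "inlet_flow_rate")) {
    ratio <- ratio_map(rb$wss, pl$wss, geom)$by_roi
  }
  structure(list(rbc = rb, plasma = pl, ratio = ratio, config = cfg,
                 mesh = geom), class = "run_pair")
}

#' @export
print.run_pair <- function(x, ...) {
  cat(sprintf("<run_pair> %d cells vs plasma, horizon %.3g ms%s\n",
              length(x$rbc$result$state$cells), x$config$horizon * 1e3,
              if (is.null(x$ratio)) " (pressure pair: no ratio report)"
              else sprintf(", mean tau ratio %.2f", mean(x$ratio$ratio))))
  invisible(x)
}

# planar-channel fixture: exact linear fields for stencil exactness checks
make_channel <- function(half_width = 5, size = 10, mesh_size = 0.8) {
  yz <- expand.grid(y = seq(0, size, by = mesh_size),
                    z = seq(0, size, by = mesh_size))
  nvy <- length(unique(yz$y))
  verts <- cbind(-half_width, yz$y, yz$z)
  idx <- function(i, j) (j - 1) * nvy + i
  tr <- NULL
  for (j in seq_len(length(unique(yz$z)) - 1))
    for (i in seq_len(nvy - 1))
      tr <- rbind(tr, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                  c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  m <- new_wall_mesh(verts, tr,
                     matrix(rep(c(-1, 0, 0), each = nrow(verts)), ncol = 3),
                     rep("vessel:1", nrow(verts)), spec = NULL)
  m$phi <- function(p) abs(p[, 1]) - half_width
  attr(m, "period") <- size
  m
}

#' Analytic fixture suite
#'
#' Runs the package's closed-form verification fixtures end to end and
#' reports each check: biconcave geometry, sphere bending energy, membrane
#' force gradients, IBM kernel moments, planar Couette WSS exactness,
#' painted linear-field WSSG exactness, and a coarse Poiseuille solve.
#'
#' @param viscosity_perturbation Multiplier applied to the plasma viscosity
#'   of the Poiseuille fixture (fault injection: values other than 1 must
#'   fail that fixture by the same factor).
#' @return Tibble with columns `fixture`, `value`, `expected`, `tol`,
#'   `pass`.
#' @export
fixture_suite <- function(viscosity_perturbation = 1) {
  rows <- list()
  chk <- function(fixture, value, expected, tol) {
    err <- if (expected == 0) abs(value) else abs(value / expected - 1)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      fixture = fixture, value = value, expected = expected, tol = tol,
      pass = err <= tol)
  }
  cell <- make_biconcave(7.8, 4)
  av <- area_volume(cell)
  chk("biconcave_area_um2", av[["area"]], 134.1, 0.01)
  chk("biconcave_volume_um3", av[["volume"]], 94.1, 0.01)
  sph <- make_biconcave(2, 4, sphere = TRUE)
  chk("sphere_bending_energy_8pikb",
      bending_forces(sph)$energy / (8 * pi * sph$k_b), 1, 0.05)
  set.seed(7)
  small <- make_biconcave(7.8, 2)
  vp <- small$vertices * 1.03 + matrix(rnorm(3 * nrow(small$vertices), 0, 0.03),
                                       ncol = 3)
  fs <- skalak_forces(small, vp)
  idx <- sample(nrow(vp), 4)
  gfd <- fd_energy_gradient(function(v) skalak_forces(small, v)$energy,
                            vp, idx, 1e-6)
  chk("skalak_force_vs_fd", max(abs(-fs$force[idx, ] * .UM - gfd)) /
        max(abs(gfd)), 0, 1e-5)
  fb <- bending_forces(small, vp)
  gfb <- fd_energy_gradient(function(v) bending_forces(small, v)$energy,
                            vp, idx, 1e-6)
  chk("bending_force_vs_fd", max(abs(-fb$force[idx, ] * .UM - gfb)) /
        max(abs(gfb)), 0, 1e-5)
  # planar Couette: exact WSS from a linear profile
  ch <- make_channel(5, 8, 0.8)
  fieldc <- structure(list(phi = ch$phi, h = 0.5,
                           bbox = rbind(c(-7, 0, 0), c(7, 8, 8))),
                      class = "distance_field")
  sysc <- flow_system(fieldc, h = 0.5, bc = list(kind = "pressure_drop",
                                                 value = 0))
  spw <- stag_points(sysc$grid$x0, sysc$grid$n, sysc$grid$h, "w")
  gam <- 100
  wfield <- array(gam * (spw$pts[, 1] + 5) * .UM, dim = sysc$grid$n)
  stc <- flow_state(sysc)
  stc$w <- wfield * sysc$grid$comp$w$fluid
  frc <- local_frames(ch, stc, sysc)
  wsc <- wall_shear_stress(stc, ch, frc, sysc)
  chk("couette_wss_dyn_cm2", mean(wsc$t_s[wsc$valid]), 1, 1e-8)
  # uniform field: the stencil annihilates constants (field wall value)
  stc$w <- array(1e-3, dim = sysc$grid$n)
  frc2 <- local_frames(ch, stc, sysc)
  wsc2 <- wall_shear_stress(stc, ch, frc2, sysc, wall_value = "field")
  chk("uniform_field_wss", max(abs(wsc2$t_s[wsc2$valid])), 0, 1e-10)
  # kernel moments
  g <- sysc$grid
  pt <- matrix(c(0.123, 3.21, 4.07), 1)
  kw <- ibm_weights(pt, g, "u")
  chk("kernel_partition_of_unity", sum(kw$w), 1, 1e-12)
  # coarse Poiseuille
  tb <- make_tube(10, 6, NULL, 0.8)
  attr(tb, "period") <- 6
  mu_p <- 0.001 * viscosity_perturbation
  syst <- flow_system(tb, h = 1, bc = list(kind = "pressure_drop", value = 0.1),
                      pad = 2.5, mu_plasma = mu_p)
  stt <- flow_state(syst)
  for (i in 1:150) stt <- step_flow(stt, syst, 2e-6)
  uc <- interp_component(stt$w, syst$grid, matrix(c(0, 0, 3), 1), "w")
  chk("poiseuille_centerline_m_s", uc, 6.25e-4, 0.05)
  out <- dplyr::bind_rows(rows)
  out
}
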