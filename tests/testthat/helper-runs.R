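# Shared expensive simulation runs, computed once per test session.
# All fixtures are generated in code; seeds are fixed so results are
# reproducible.

.run_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# steady plasma Poiseuille tube: D = 10 um, G = 0.1 Pa/um, h = 0.5 um
poiseuille_run <- function() cached("poiseuille", {
  m <- make_tube(10, 8, NULL, 0.5)
  attr(m, "period") <- 8
  sys <- flow_system(m, h = 0.5, bc = list(kind = "pressure_drop", value = 0.1),
                     pad = 2.25)
  st <- flow_state(sys)
  for (i in 1:200) st <- step_flow(st, sys, 2e-6)
  for (i in 1:500) st <- step_flow(st, sys, 1e-4)   # settle to steady state
  fr <- local_frames(m, st, sys)
  ws <- wall_shear_stress(st, m, fr, sys)
  list(mesh = m, sys = sys, state = st, frames = fr, wss = ws,
       u_exact = 6.25e-4, tau_exact = 2.5)
})

# matched-flow-rate pair in a D = 10 um tube: plasma reference, then a
# single red cell at the same flow rate, 20 ms horizon
tube_pair <- function() cached("tube_pair", {
  m <- make_tube(10, 12, NULL, 0.5)
  attr(m, "period") <- 12
  sys_p <- flow_system(m, h = 0.5,
                       bc = list(kind = "pressure_drop", value = 0.1),
                       pad = 2.25)
  st <- flow_state(sys_p)
  for (i in 1:200) st <- step_flow(st, sys_p, 2e-6)
  for (i in 1:400) st <- step_flow(st, sys_p, 1e-4)
  k_gate <- 2L
  Q_pl <- microwss:::gate_flow(st, sys_p, k_gate)
  fr_p <- local_frames(m, st, sys_p)
  ws_p <- wall_shear_stress(st, m, fr_p, sys_p, averaged = TRUE)
  ws_p$bc_kind <- "inlet_flow_rate"   # matched-Q reference member
  sys_r <- flow_system(m, h = 0.5,
                       bc = list(kind = "inlet_flow_rate", value = Q_pl),
                       pad = 2.25)
  cell <- make_biconcave(7.8, 3)
  cell$vertices[, 3] <- cell$vertices[, 3] + 6
  res <- run_simulation(sys_r, cells = list(cell), horizon = 0.02,
                        dt = 2.5e-6, cadence = 5e-4)
  fr_r <- local_frames(m, res$mean, sys_r)
  ws_r <- wall_shear_stress(res$mean, m, fr_r, sys_r, averaged = TRUE)
  list(mesh = m, sys_p = sys_p, sys_r = sys_r, state_p = st, res_r = res,
       wss_p = ws_p, wss_r = ws_r, fr_p = fr_p, fr_r = fr_r, Q_pl = Q_pl,
       cell_ref = cell)
})

# steady plasma flow in a sinusoidally curved tube
curved_run <- function() cached("curved", {
  amp <- 2.5
  m <- make_tube(8, 32, function(z) amp * sin(2 * pi * z / 32), 0.45)
  attr(m, "period") <- 32
  sys <- flow_system(m, h = 0.5, bc = list(kind = "pressure_drop", value = 0.2),
                     pad = 2.25)
  st <- flow_state(sys)
  for (i in 1:250) st <- step_flow(st, sys, 2e-6)
  for (i in 1:400) st <- step_flow(st, sys, 1e-4)
  fr <- local_frames(m, st, sys)
  ws <- wall_shear_stress(st, m, fr, sys)
  list(mesh = m, sys = sys, state = st, frames = fr, wss = ws, amp = amp)
})

# periodic bifurcation-convergence loop: steady plasma flow plus
# finite-size tracer flux partitioning
loop_run <- function() cached("loop", {
  loop <- make_junction_loop(feeder_diameter = 11, branch_diameters = c(9, 8),
                             branch_sep = 12, feeder_len = 8,
                             branch_len = 14, mesh_size = 0.9)
  sys <- flow_system(loop, h = 0.8, bc = list(kind = "pressure_drop",
                                              value = 0.5), pad = 2.4)
  sdf <- signed_distance(loop, h = 0.8, bbox = sys$field$bbox)
  gates <- attr(loop, "gates")
  res <- run_simulation(sys, horizon = 1.6e-3, dt = 2e-6, cadence = 1e-4,
                        sample_fn = gate_sample_fn(gates))
  starts <- seed_tracer_starts(sdf, 30, make_biconcave(n_refine = 2),
                               seed = 4)
  tf <- tracer_fluxes(sys, res$state, gates, starts, horizon = 0.04)
  list(mesh = loop, sys = sys, res = res, gates = gates, sdf = sdf,
       tracers = tf, n_tracers = nrow(starts))
})

# tiny toy wall mesh with prescribed vertex areas (hand-quadrature oracles)
toy_two_patch_mesh <- function() {
  # two right triangles of areas 1.5 and 4.5 um^2 -> vertex areas by thirds
  v <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 1, 0), c(3, 3, 0))
  tr <- rbind(c(1, 2, 3), c(2, 4, 3))
  microwss:::new_wall_mesh(v, tr,
                           matrix(rep(c(0, 0, 1), each = 4), ncol = 3),
                           rep("vessel:1", 4))
}

# count closed boundary loops of an open mesh
n_boundary_loops <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  be <- names(cnt)[cnt == 1]
  if (!length(be)) return(0L)
  pairs <- do.call(rbind, strsplit(be, " "))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  verts <- unique(as.vector(pairs))
  adj <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  seen <- character(0)
  loops <- 0L
  for (v0 in verts) {
    if (as.character(v0) %in% seen) next
    loops <- loops + 1L
    frontier <- v0
    while (length(frontier)) {
      seen <- c(seen, as.character(frontier))
      nxt <- unique(unlist(adj[as.character(frontier)]))
      frontier <- setdiff(nxt, as.integer(seen))
    }
  }
  loops
}
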