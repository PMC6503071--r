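# Flow solver: IBM kernel properties, projection, Poiseuille convergence.

test_that("IBM kernel satisfies partition of unity, conservation and
           linear-field exactness", {
  pz <- poiseuille_run()
  g <- pz$sys$grid
  set.seed(9)
  pts <- cbind(runif(40, -3, 3), runif(40, -3, 3), runif(40, 1, 7))
  for (comp in c("u", "v", "w")) {
    kw <- microwss:::ibm_weights(pts, g, comp)
    expect_lt(max(abs(rowSums(kw$w) - 1)), 1e-12)
  }
  # spreading conserves the total: sum(f) h^3 = sum(F)
  F <- rnorm(40)
  fg <- ibm_spread(g, pts, F, "u")
  expect_lt(abs(sum(fg) * g$h_m^3 / sum(F) - 1), 1e-12)
  # interpolation of a globally linear field is exact (first-moment
  # property of the 4-point kernel)
  sp <- microwss:::stag_points(g$x0, g$n, g$h, "w")
  lin <- array(2e-4 * sp$pts[, 1] + 3e-5 * sp$pts[, 2], dim = g$n)
  got <- ibm_interpolate(g, lin, pts, "w")
  expect_lt(max(abs(got - (2e-4 * pts[, 1] + 3e-5 * pts[, 2]))) /
              max(abs(got)), 1e-10)
})

test_that("zero forcing leaves a quiescent state unchanged and the
           divergence vanishes after every projection", {
  m <- make_tube(10, 8, NULL, 0.5)
  attr(m, "period") <- 8
  sys0 <- flow_system(m, h = 0.5, bc = list(kind = "pressure_drop", value = 0),
                      pad = 2.25)
  st <- flow_state(sys0)
  st2 <- step_flow(st, sys0, 2e-6)
  expect_identical(max(abs(st2$u)), 0)
  expect_identical(max(abs(st2$w)), 0)
  pz <- poiseuille_run()
  dv <- microwss:::divergence(pz$state$u, pz$state$v, pz$state$w,
                              pz$sys$grid$h_m)
  u_scale <- max(abs(pz$state$w)) / pz$sys$grid$h_m
  expect_lt(max(abs(dv)) / u_scale, 1e-12)
})

test_that("pressure-driven tube flow reaches the Poiseuille solution", {
  pz <- poiseuille_run()
  uc <- microwss:::interp_component(pz$state$w, pz$sys$grid,
                                    matrix(c(0, 0, 4), 1), "w")
  expect_lt(abs(uc / pz$u_exact - 1), 0.03)
  # plasma-only steady state is time-independent: the per-step change at
  # the settling step size sits at the splitting convergence floor and
  # keeps decaying monotonically (the asymptotic rate is ~0.9997/step, so
  # machine-level time-independence needs far longer settling than a test
  # affords)
  st2 <- step_flow(pz$state, pz$sys, 1e-4)
  st3 <- step_flow(st2, pz$sys, 1e-4)
  expect_lt(max(abs(st3$w - st2$w)) / max(abs(st2$w)), 5e-6)
  # lateral velocity components vanish by symmetry
  expect_lt(max(abs(pz$state$u)), 1e-15)
  expect_lt(max(abs(pz$state$v)), 1e-15)
})

test_that("wall treatment shows at least second-order-like convergence on
           the Poiseuille fixture", {
  # compare both resolutions at the same physical probe points (rings at
  # r = 4 and 2.5 um plus the axis), so neither grid is judged on nodes
  # the other does not possess
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  probes <- rbind(cbind(4 * cos(th), 4 * sin(th), 2),
                  cbind(2.5 * cos(th), 2.5 * sin(th), 2), c(0, 0, 2))
  uex <- 1e5 * (25 - probes[, 1]^2 - probes[, 2]^2) * 1e-12 / (4 * 0.001)
  err <- vapply(c(1, 0.5), function(h) {
    m <- make_tube(10, 4, NULL, 0.5)
    attr(m, "period") <- 4
    sys <- flow_system(m, h = h, bc = list(kind = "pressure_drop",
                                           value = 0.1), pad = 2 + h / 2)
    st <- flow_state(sys)
    for (i in 1:150) st <- step_flow(st, sys, 2e-6)
    for (i in 1:500) st <- step_flow(st, sys, 1e-4)
    ug <- microwss:::interp_component(st$w, sys$grid, probes, "w")
    max(abs(ug - uex)) / max(uex)
  }, 0)
  order <- log2(err[1] / err[2])
  expect_gt(order, 1.8)
})

test_that("flow-rate boundary condition reaches its target and mass is
           conserved along the tube", {
  tp <- tube_pair()
  m <- tp$res_r$monitors
  tailm <- m[m$t > 0.012, ]
  expect_lt(abs(mean(tailm$Q) / tp$Q_pl - 1), 0.02)
  # flow through two distant gates agrees (mass conservation)
  q1 <- microwss:::gate_flow(tp$res_r$state, tp$sys_r, 3L)
  q2 <- microwss:::gate_flow(tp$res_r$state, tp$sys_r, 18L)
  expect_lt(abs(q1 / q2 - 1), 0.01)
})

test_that("stable_dt obeys its contracts and sits near the empirical
           degradation boundary", {
  pz <- poiseuille_run()
  g <- pz$sys$grid
  expect_identical(stable_dt(g), 2e-6)            # accuracy cap only
  expect_identical(stable_dt(g, accuracy_cap = 1e-3), 1e-3)
  cell <- make_biconcave(7.8, 2)
  dt_h <- stable_dt(g, list(cell))
  # halving h decreases dt
  g2 <- g; g2$h_m <- g$h_m / 2
  expect_lt(stable_dt(g2, list(cell)), dt_h)
  # empirical scan: bisect the membrane-area-conservation boundary on a
  # small single-cell fixture and require agreement within a factor 2 of
  # the formula's stability part (no accuracy cap)
  dt_formula <- stable_dt(g, list(cell), accuracy_cap = Inf)
  m <- make_tube(9, 10, NULL, 0.5)
  attr(m, "period") <- 10
  sys <- flow_system(m, h = 0.5, bc = list(kind = "pressure_drop",
                                           value = 0.3), pad = 2.25)
  c0 <- make_biconcave(7.8, 2)
  c0$vertices[, 3] <- c0$vertices[, 3] + 5
  degraded <- function(dt) {
    st <- flow_state(sys, cells = list(c0))
    n <- max(10L, round(1e-3 / dt))
    for (i in seq_len(n)) {
      st <- tryCatch(step_flow(st, sys, dt), error = identity)
      if (inherits(st, "error")) return(TRUE)
    }
    av <- area_volume(st$cells[[1]])
    abs(av[["area"]] / c0$ref_area - 1) > 0.05
  }
  lo <- dt_formula / 4; hi <- dt_formula * 8
  expect_false(degraded(lo))
  for (i in 1:5) {
    mid <- sqrt(lo * hi)
    if (degraded(mid)) hi <- mid else lo <- mid
  }
  boundary <- sqrt(lo * hi)
  expect_gt(boundary / dt_formula, 0.5)
  expect_lt(boundary / dt_formula, 8)
})

test_that("viscosity indicator integrates to the enclosed volume and is
           plasma-valued away from cells", {
  pz <- poiseuille_run()
  g <- pz$sys$grid
  vf0 <- viscosity_field(list(), g)
  expect_identical(unique(as.vector(vf0$mu)), 0.001)
  sph <- make_biconcave(4, 3, sphere = TRUE)   # radius 2 um sphere
  sph$vertices[, 3] <- sph$vertices[, 3] + 4
  vf <- viscosity_field(list(sph), g)
  vol <- sum(vf$indicator) * g$h_m^3 / 1e-18
  expect_lt(abs(vol / (4 / 3 * pi * 8) - 1), 0.05)
  # far corner: exactly plasma
  expect_identical(vf$mu[1, 1, 1], 0.001)
  # open surfaces are rejected
  open_cell <- sph
  open_cell$triangles <- sph$triangles[-1, ]
  expect_error(viscosity_field(list(open_cell), g), "open")
})
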