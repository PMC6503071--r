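# Junction flux partitioning, phase-separation regression, vessel tables.

test_that("phase-separation regression recovers exact synthetic lines", {
  d <- tibble::tibble(dtau = c(-1, 0, 1), phase_sep = c(-2, 0, 2))
  fit <- phase_separation_vs_wss(d)
  g <- glance(fit)
  expect_equal(g$slope, 2, tolerance = 1e-12)
  expect_equal(g$intercept, 0, tolerance = 1e-12)
  expect_equal(g$r, 1, tolerance = 1e-12)
  # proportional partitioning: all y = 0 -> slope 0
  d0 <- tibble::tibble(dtau = c(-1, 0.5, 2), phase_sep = c(0, 0, 0))
  expect_equal(glance(phase_separation_vs_wss(d0))$slope, 0,
               tolerance = 1e-12)
  # degenerate x-variance flagged, not fit
  dd <- tibble::tibble(dtau = c(1, 1, 1), phase_sep = c(0, 1, 2))
  expect_true(glance(phase_separation_vs_wss(dd))$degenerate)
  expect_error(phase_separation_vs_wss(d[1:2, ]), "3")
})

test_that("branch fluxes turn synthetic crossings into the hand-computed
           N* - Q* values", {
  gates <- list(
    feeder = list(point = c(0, 0, 0), normal = c(0, 0, 1), radius = 5),
    branch1 = list(point = c(5, 0, 10), normal = c(0, 0, 1), radius = 4),
    branch2 = list(point = c(-5, 0, 10), normal = c(0, 0, 1), radius = 4))
  # 10 cells crossing the feeder; 8 continue through branch 1, 2 through
  # branch 2; flows give Q1* = 0.6
  nt <- 41
  ts <- seq(0, 0.04, length.out = nt)
  samples <- lapply(seq_len(nt), function(i) {
    pos <- NULL
    for (ci in 1:10) {
      z <- -2 - (ci - 1) * 1.2 + ts[i] * 750
      x <- if (ci <= 8) 5 * min(max(z, 0), 10) / 10 else
        -5 * min(max(z, 0), 10) / 10
      pos <- rbind(pos, c(x, 0, z))
    }
    list(t = ts[i], gate_flows = c(feeder = 1e-13, branch1 = 0.6e-13,
                                   branch2 = 0.4e-13), cell_pos = pos)
  })
  res <- list(samples = samples, sys = list(mesh = NULL))
  bf <- branch_fluxes(res, gates, transient_frac = 0)
  expect_equal(bf$Q1_star, 0.6, tolerance = 1e-12)
  expect_equal(bf$Q1_star + bf$Q2_star, 1, tolerance = 1e-12)
  expect_equal(bf$N1_star, 0.8, tolerance = 1e-12)
  expect_equal(bf$phase_sep, 0.2, tolerance = 1e-12)
})

test_that("plasma loop flow is conserved at the junctions", {
  lr <- loop_run()
  expect_false(lr$res$diverged)
  bf <- branch_fluxes(lr$res, lr$gates)
  expect_lt(abs(bf$Q1_star + bf$Q2_star - 1), 0.02)
  expect_gt(bf$Q1_star, bf$Q2_star)   # wider branch takes more flow
})

test_that("finite-size tracer flux partitions disproportionately toward the
           higher-flow branch (plasma skimming direction)", {
  lr <- loop_run()
  tf <- lr$tracers
  expect_gt(tf$N_F, 0)
  # every tracer crossing the feeder is accounted for in a branch
  expect_lt(abs(tf$N1_star + tf$N2_star - 1), 0.15)
  # the skimming sign: cells over-follow the stronger branch
  expect_gt(tf$phase_sep, 0)
  expect_true(tf$Q1_star > 0.5 & tf$Q1_star < 1)
})

test_that("vessel tables aggregate painted per-vessel fields exactly", {
  spec <- build_network(2, 1.6, 0.15, seed = 3, mesh = TRUE, mesh_size = 1.1)
  m <- attr(spec, "mesh")
  painted <- c("vessel:1" = 12, "vessel:2" = 8, "vessel:3" = 8,
               "vessel:4" = 20, "vessel:5" = 15)
  tau <- rep(5, nrow(m$vertices))
  for (r in names(painted)) tau[m$roi == r] <- painted[[r]]
  ws <- structure(list(t_s = tau, valid = rep(TRUE, length(tau)),
                       bc_kind = "inlet_flow_rate"), class = "wss_field")
  vt <- vessel_table(ws, ws, m)
  expect_gt(nrow(vt), 1)
  for (i in seq_len(nrow(vt))) {
    r <- paste0("vessel:", vt$id[i])
    if (r %in% names(painted))
      expect_equal(vt$tau_rbc[i], painted[[r]], tolerance = 1e-12)
  }
  # plasma paired with itself: all ratio columns are 1
  expect_true(all(abs(vt$ratio - 1) < 1e-12))
})
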