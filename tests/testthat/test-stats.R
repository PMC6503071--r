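# ROI statistics: averages, normalized standard deviation, temporal RMS,
# influence ratios, cross-sectional profiles.

test_that("ROI average is the area-weighted mean (hand quadrature)", {
  m <- toy_two_patch_mesh()
  # vertex areas: v1 0.5, v2 0.5+1.5=2, v3 0.5+1.5=2, v4 1.5
  expect_equal(m$vertex_area, c(0.5, 2, 2, 1.5), tolerance = 1e-12)
  # constant field
  expect_equal(roi_average(rep(3.3, 4), m, "vessel:1"), 3.3, tolerance = 1e-12)
  # two-patch quadrature: values 2 on area 1, 6 on area 3 -> 5
  m2 <- m
  m2$vertex_area <- c(1, 3, 0, 0)
  m2$roi <- c("vessel:1", "vessel:1", "cap", "cap")
  expect_equal(roi_average(c(2, 6, 0, 0), m2, "vessel:1"), 5,
               tolerance = 1e-12)
  expect_error(roi_average(rep(1, 4), m, "vessel:99"), "no valid")
})

test_that("per-vessel normalized standard deviation follows the printed
           formula and is scale invariant", {
  m <- toy_two_patch_mesh()
  m$vertex_area <- rep(1, 4)
  m$roi <- c("vessel:1", "vessel:1", "cap", "cap")
  tau <- c(1, 3, 0, 0)
  # tau_bar = 2, sqrt(sum((tau-2)^2)/(N-1))/2 = sqrt(2)/2
  expect_equal(vessel_std(tau, m, "vessel:1"), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(vessel_std(5.7 * tau, m, "vessel:1"),
               vessel_std(tau, m, "vessel:1"), tolerance = 1e-12)
  expect_equal(vessel_std(rep(4, 4), m, "vessel:1"), 0, tolerance = 1e-15)
  expect_error(vessel_std(c(1, -1, 0, 0), m, "vessel:1"), "zero")
})

test_that("temporal RMS matches the sinusoid closed form and scales
           linearly in the amplitude", {
  m <- toy_two_patch_mesh()
  ts <- seq(0, 1, length.out = 65)[-65]
  a <- 0.8; mu <- 2.5
  series <- sapply(ts, function(t) rep(mu + a * sin(2 * pi * t), 4))
  out <- temporal_rms(series, m, "vessel:1")
  expect_equal(out$rms_abs, a / sqrt(2), tolerance = 1e-3)
  expect_equal(out$rms_rel, a / (sqrt(2) * mu), tolerance = 1e-3)
  out2 <- temporal_rms(sapply(ts, function(t)
    rep(mu + 2 * a * sin(2 * pi * t), 4)), m, "vessel:1")
  expect_equal(out2$rms_abs / out$rms_abs, 2, tolerance = 1e-10)
  # time-constant signal
  out0 <- temporal_rms(matrix(3, 4, 10), m, "vessel:1")
  expect_equal(out0$rms_abs, 0, tolerance = 1e-14)
  expect_equal(out0$rms_rel, 0, tolerance = 1e-14)
  expect_error(temporal_rms(matrix(1, 4, 5), m), "8")
})

test_that("influence ratios: identity, proportional fields, and the
           flow-BC requirement", {
  pz <- poiseuille_run()
  ws <- pz$wss
  ws$bc_kind <- "inlet_flow_rate"
  r1 <- ratio_map(ws, ws, pz$mesh)
  expect_lt(max(abs(r1$pointwise[!is.na(r1$pointwise)] - 1)), 1e-12)
  expect_lt(max(abs(r1$by_roi$ratio - 1)), 1e-12)
  ws3 <- ws; ws3$t_s <- 3 * ws$t_s
  expect_lt(abs(ratio_map(ws3, ws, pz$mesh)$by_roi$ratio - 3), 1e-12)
  wp <- pz$wss   # pressure-BC field
  expect_error(ratio_map(wp, wp, pz$mesh), "flow")
  # full pipeline self-consistency: a plasma pair through the pipeline
  r2 <- ratio_map(ws, ws, pz$mesh, enforce_bc = FALSE)
  expect_lt(max(abs(r2$by_roi$ratio - 1)), 1e-10)
})

test_that("cross-section profiles report bluntness and skewness correctly", {
  pz <- poiseuille_run()
  prof <- cross_section_profiles(pz$state, pz$sys, point = c(0, 0, 4),
                                 chord_dir = c(1, 0, 0), half_len = 6)
  expect_lt(abs(prof$bluntness / 2 - 1), 0.03)
  expect_identical(prof$skew_side, 0)
  # plug profile -> bluntness 1 (painted everywhere so interpolation at the
  # chord is exact)
  g <- pz$sys$grid
  st <- pz$state
  st$w <- array(1e-3, dim = g$n)
  prof2 <- cross_section_profiles(st, pz$sys, point = c(0, 0, 4),
                                  chord_dir = c(1, 0, 0), half_len = 6)
  expect_lt(abs(prof2$bluntness - 1), 0.01)
  expect_identical(prof2$skew_side, 0)
  # a chord crossing two lumina (through a junction) is rejected
  twoslab <- structure(list(
    phi = function(p) pmin(abs(p[, 1] - 3) - 2, abs(p[, 1] + 3) - 2),
    h = 0.5, bbox = rbind(c(-7, 0, 0), c(7, 4, 4))),
    class = "distance_field")
  sys2 <- flow_system(twoslab, h = 0.5,
                      bc = list(kind = "pressure_drop", value = 0))
  st2 <- flow_state(sys2)
  expect_error(cross_section_profiles(st2, sys2, point = c(0, 2, 2),
                                      chord_dir = c(1, 0, 0), half_len = 6.5),
               "more than one lumen")
})

test_that("roi_summary aggregates one row per ROI with areas", {
  pz <- poiseuille_run()
  rs <- roi_summary(pz$wss, pz$mesh)
  expect_identical(nrow(rs), 1L)
  expect_equal(rs$area, sum(pz$mesh$vertex_area), tolerance = 1e-10)
  expect_lt(abs(rs$tau_bar / 2.5 - 1), 0.05)
})
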