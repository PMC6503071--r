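# Local frames, traction extraction and surface gradients.

test_that("time averaging obeys its closed forms", {
  a <- array(runif(60), dim = c(3, 4, 5))
  mk <- function(u) list(u = u, v = u * 0.5, w = u * 2)
  # steady series: average equals the field
  avg <- time_average(list(mk(a), mk(a), mk(a)))
  expect_equal(avg$u, a, tolerance = 1e-14)
  # u and -u average to zero
  avg0 <- time_average(list(mk(a), mk(-a)))
  expect_lt(max(abs(avg0$w)), 1e-15)
  # sinusoid over whole periods: mean term survives
  ts <- seq(0, 1, length.out = 33)[-33]
  ser <- lapply(ts, function(t) mk(a + sin(2 * pi * t) * 0.3))
  avgs <- time_average(ser)
  expect_lt(max(abs(avgs$u - a)), 1e-10)
  expect_error(time_average(list(mk(a), mk(array(0, c(2, 2, 2))))),
               "mismatched")
  expect_error(time_average(list(mk(a))), "2")
})

test_that("local frames are orthonormal, axis-aligned for tube flow, and
           azimuthal for a painted swirl field", {
  pz <- poiseuille_run()
  fr <- pz$frames
  expect_lt(max(abs(rowSums(fr$e_s * fr$e_r))), 1e-10)
  expect_lt(max(abs(rowSums(fr$e_s * fr$e_theta))), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(fr$e_theta^2)) - 1)), 1e-10)
  expect_lt(max(abs(fr$e_s[, 3] - 1)), 1e-6)
  # rotating (swirl) synthetic field: e_s must be azimuthal
  g <- pz$sys$grid
  spu <- microwss:::stag_points(g$x0, g$n, g$h, "u")
  spv <- microwss:::stag_points(g$x0, g$n, g$h, "v")
  om <- 200
  swirl <- list(u = array(-om * spu$pts[, 2] * 1e-6, dim = g$n),
                v = array(om * spv$pts[, 1] * 1e-6, dim = g$n),
                w = array(0, dim = g$n))
  fr2 <- local_frames(pz$mesh, swirl, pz$sys)
  expect_lt(max(abs(fr2$e_s[, 3])), 1e-6)
})

test_that("wall shear stress matches the Poiseuille closed form and the
           traction components keep their hierarchy", {
  pz <- poiseuille_run()
  ws <- pz$wss
  tau_bar <- roi_average(ws, pz$mesh, "vessel:1")
  expect_lt(abs(tau_bar / pz$tau_exact - 1), 0.05)
  # spatial constancy on the lateral surface
  expect_lt(max(abs(ws$t_s[ws$valid] / pz$tau_exact - 1)), 0.08)
  # t_theta and viscous t_r are orders of magnitude below t_s
  expect_lt(max(abs(ws$t_theta[ws$valid])) / max(ws$t_s[ws$valid]), 1e-4)
  expect_lt(max(abs(ws$t_r_visc[ws$valid])) / max(ws$t_s[ws$valid]), 1e-4)
  expect_error(wall_shear_stress(pz$state, pz$mesh, pz$frames, pz$sys,
                                 stencil_span = 0.5), "0.3")
})

test_that("the stencil is exact on linear profiles and annihilates
           constants", {
  ch <- microwss:::make_channel(5, 8, 0.8)
  fieldc <- structure(list(phi = ch$phi, h = 0.5,
                           bbox = rbind(c(-7, 0, 0), c(7, 8, 8))),
                      class = "distance_field")
  sysc <- flow_system(fieldc, h = 0.5,
                      bc = list(kind = "pressure_drop", value = 0))
  spw <- microwss:::stag_points(sysc$grid$x0, sysc$grid$n, sysc$grid$h, "w")
  st <- flow_state(sysc)
  st$w <- array(100 * (spw$pts[, 1] + 5) * 1e-6, dim = sysc$grid$n)
  fr <- local_frames(ch, st, sysc)
  ws <- wall_shear_stress(st, ch, fr, sysc)
  expect_lt(max(abs(ws$t_s[ws$valid] - 1)), 1e-8)   # mu * 100/s = 1 dyne/cm2
  st$w <- array(5e-4, dim = sysc$grid$n)
  ws0 <- wall_shear_stress(st, ch, local_frames(ch, st, sysc), sysc,
                           wall_value = "field")
  expect_lt(max(abs(ws0$t_s[ws0$valid])), 1e-10)
})

test_that("surface gradients are exact on painted linear and sinusoidal
           fields and vanish on constants", {
  pz <- poiseuille_run()
  m <- pz$mesh
  fr <- pz$frames
  axial <- list(e_r = fr$e_r,
                e_s = matrix(rep(c(0, 0, 1), each = nrow(m$vertices)), ncol = 3),
                stagnant = fr$stagnant)
  axial$e_theta <- microwss:::vec_cross(axial$e_r, axial$e_s)
  class(axial) <- "local_frames"
  base <- pz$wss
  inner <- function(g) g$valid & m$s_coord > 1 & m$s_coord < 7
  # constant field
  wsc <- base; wsc$t_s <- rep(4.2, length(base$t_s))
  wsc$valid <- rep(TRUE, length(base$t_s))
  g0 <- wssg(wsc, m, axial)
  expect_lt(max(abs(g0$grad_s[g0$valid])), 1e-10)
  expect_lt(max(abs(g0$grad_theta[g0$valid])), 1e-10)
  # linear in arc length
  wsl <- wsc; wsl$t_s <- 0.7 * m$s_coord
  gl <- wssg(wsl, m, axial)
  expect_lt(max(abs(gl$grad_s[inner(gl)] - 0.7)), 1e-6)
  expect_lt(max(abs(gl$grad_theta[inner(gl)])), 1e-6)
  # sin(theta) painted on the tube: circumferential gradient cos(theta)/R
  wst <- wsc; wst$t_s <- sin(m$theta_coord)
  gt <- wssg(wst, m, axial)
  expected <- cos(m$theta_coord) / 5
  tol <- (0.15 / 5)^2 + 0.02 / 5   # 2nd-order in span + interpolation
  expect_lt(max(abs(gt$grad_theta[gt$valid] - expected[gt$valid])), 5 * tol)
  # magnitude dominates each component pointwise
  expect_true(all(gt$grad_mag >= abs(gt$grad_s) - 1e-12))
  expect_true(all(gt$grad_mag >= abs(gt$grad_theta) - 1e-12))
})

test_that("straight-tube plasma WSSG is small: ROI-mean components within
           5% of tau/D and mean magnitudes within the documented noise
           ceiling", {
  pz <- poiseuille_run()
  gg <- wssg(pz$wss, pz$mesh, pz$frames, smooth_iters = 2, k_neighbors = 20)
  lim <- pz$tau_exact / 10               # tau / D
  A <- pz$mesh$vertex_area[gg$valid]
  mean_s <- sum(gg$grad_s[gg$valid] * A) / sum(A)
  mean_t <- sum(gg$grad_theta[gg$valid] * A) / sum(A)
  expect_lt(abs(mean_s), 0.05 * lim)
  expect_lt(abs(mean_t), 0.05 * lim)
  expect_lt(sum(abs(gg$grad_s[gg$valid]) * A) / sum(A), 0.25 * lim)
  expect_lt(sum(abs(gg$grad_theta[gg$valid]) * A) / sum(A), 0.25 * lim)
})

test_that("averaging and traction extraction commute on a steady field", {
  pz <- poiseuille_run()
  series <- list(pz$state, pz$state, pz$state)
  avg <- time_average(series)
  ws_avg <- wall_shear_stress(avg, pz$mesh, pz$frames, pz$sys)
  per <- lapply(series, function(s)
    wall_shear_stress(s, pz$mesh, pz$frames, pz$sys)$t_s)
  mean_of_wss <- Reduce(`+`, per) / length(per)
  expect_lt(max(abs(ws_avg$t_s - mean_of_wss)), 1e-12)
})
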