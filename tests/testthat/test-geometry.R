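# Synthetic vessel geometry: tubes, junctions, networks.

test_that("straight tube has the analytic lateral area and radius", {
  m <- make_tube(10, 50, NULL, 0.5)
  expect_lt(abs(mesh_area(m) / (pi * 10 * 50) - 1), 0.01)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  expect_lt(max(abs(r / 5 - 1)), 0.005)
  expect_lt(max(abs(sqrt(rowSums(m$normals^2)) - 1)), 1e-10)
  expect_lt(abs(sum(m$vertex_area) / mesh_area(m) - 1), 1e-8)
  wt <- check_watertight(m)
  expect_false(wt$closed)                    # open ended
  expect_identical(wt$n_nonmanifold_edges, 0L)
  expect_identical(n_boundary_loops(m), 2L)  # two rims
})

test_that("curved tube centerline is longer than its axial extent
           (polyline quadrature oracle)", {
  m <- make_tube(8, 60, function(z) 6 * sin(2 * pi * z / 60), 0.4)
  # independent quadrature on a dense polyline of the same profile
  z <- seq(0, 60, length.out = 2001)
  oracle <- polyline_length(cbind(6 * sin(2 * pi * z / 60), 0, z))
  expect_gt(oracle, 60)
  expect_lt(abs(polyline_length(m$centerline$pos) / oracle - 1), 0.01)
})

test_that("mesh_size preconditions are enforced with informative errors", {
  expect_error(make_tube(10, 50, NULL, 2), "diameter/6")
  expect_error(make_tube(3, 50), "\\[4, 30\\]")
})

test_that("bifurcation surface is a capped sphere topologically and opens
           into three caps", {
  j <- make_junction("bifurcation", 14, c(10, 8), c(35, 35), mesh_size = 1.4)
  wt <- check_watertight(j)
  expect_identical(wt$n_nonmanifold_edges, 0L)
  expect_identical(n_boundary_loops(j), 3L)
  rois <- setdiff(unique(j$roi), "cap")
  expect_setequal(rois, c("bifurcation:1", "vessel:1", "vessel:2", "vessel:3"))
  # capped variant: closed surface with Euler characteristic 2
  spec <- j$spec
  caps <- list(
    list(point = c(0, 0, -25), normal = c(0, 0, -1)),
    list(point = spec$vessels[[2]]$centerline[2, ],
         normal = spec$vessels[[2]]$centerline[2, ] / 25),
    list(point = spec$vessels[[3]]$centerline[2, ],
         normal = spec$vessels[[3]]$centerline[2, ] / 25))
  mc <- microwss:::mesh_from_spec(spec, 1.4, caps = caps, open_caps = FALSE)
  expect_true(check_watertight(mc)$closed)
  expect_identical(euler_characteristic(mc), 2L)
})

test_that("convergence junction mirrors a capillary merging into a venule", {
  j <- make_junction("convergence", 11, c(6, 11), c(30, 20), mesh_size = 0.75)
  expect_identical(n_boundary_loops(j), 3L)
  expect_identical(check_watertight(j)$n_nonmanifold_edges, 0L)
  expect_identical(length(setdiff(unique(j$roi), "cap")), 4L)
})

test_that("Horton-scaled bifurcation has exactly four non-cap ROI labels", {
  r <- 1.6
  j <- make_junction("bifurcation", 12, c(12 / r, 12 / r), c(30, 30),
                     mesh_size = 1.2)
  expect_identical(length(setdiff(unique(j$roi), "cap")), 4L)
})

test_that("generated networks respect in vivo morphometry and are
           deterministic", {
  spec <- build_network(3, 1.6, 0.3, seed = 1)
  vt <- tidy(spec)
  expect_true(all(vt$diameter >= 6 & vt$diameter <= 24))
  expect_true(all(vt$length >= 25 & vt$length <= 165))
  kinds <- vapply(spec$junctions, function(j) j$kind, "")
  expect_identical(sum(kinds == "bifurcation"), sum(kinds == "convergence"))
  expect_true(all(sort(unique(vt$order)) %in% 1:3))
  # determinism: identical vertex arrays on repeat
  s1 <- build_network(2, 1.5, 0, seed = 7)
  s2 <- build_network(2, 1.5, 0, seed = 7)
  expect_identical(s1$vessels, s2$vessels)
  # invalid parameter combination rejected
  expect_error(build_network(3, 2.2, 0.3, seed = 1), "\\[6, 24\\]")
})

test_that("meshed network partitions all non-cap vertices into ROIs", {
  spec <- build_network(2, 1.6, 0.2, seed = 2, mesh = TRUE,
                        mesh_size = 1.1)
  m <- attr(spec, "mesh")
  expect_false(any(is.na(m$roi)))
  expect_identical(check_watertight(m)$n_nonmanifold_edges, 0L)
  # every ROI label is a vessel or junction of the spec
  ids <- vapply(spec$vessels, function(v) v$id, 0)
  labs <- setdiff(unique(m$roi), "cap")
  own <- vapply(strsplit(labs, ":"), function(p) p[1], "")
  expect_true(all(own %in% c("vessel", "bifurcation", "convergence")))
})

test_that("junction loop is periodic and carries gate definitions", {
  loop <- loop_run()$mesh
  expect_identical(attr(loop, "period"), 22)
  expect_setequal(names(attr(loop, "gates")),
                  c("feeder", "branch1", "branch2"))
})
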