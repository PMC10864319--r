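test_that("cone half-angle follows the rim-circle taper", {
  expect_equal(cone_half_angle_from_dims(flask_dimensions()), 16.76,
               tolerance = 0.005 / 16.76)
  # hand arctan: taper (40 - 20) mm over 100 mm of height
  dims <- flask_dimensions(torus_radius = 10, max_diameter = 80,
                           height_of_max_diameter = 10, top_diameter = 40,
                           top_height = 110)
  expect_equal(cone_half_angle_from_dims(dims), atan(20 / 100) * 180 / pi,
               tolerance = 1e-12)
  # near-cylinder limit: vanishing taper
  dims <- flask_dimensions(torus_radius = 10, max_diameter = 80,
                           height_of_max_diameter = 10,
                           top_diameter = 80 - 1e-6, top_height = 110)
  expect_lt(cone_half_angle_from_dims(dims), 1e-3)
})

test_that("dimension invariants are enforced", {
  expect_error(flask_dimensions(bottom_diameter = 50), "torus construction")
  expect_error(flask_dimensions(top_diameter = 90), "max_diameter")
  expect_error(flask_dimensions(top_height = 10), "top_height")
})

test_that("smooth transition solves the printed tangency angle", {
  s <- solve_smooth_transition(flask_dimensions())
  expect_equal(s$torus_arc_angle, 107.2, tolerance = 0.1 / 107.2)
  # cone half-angle equals the chord slope from the solved end point
  g <- geom_smooth
  rt <- g$dims$torus_radius
  chord <- atan2(g$junction_r - g$dims$top_diameter / 2,
                 g$dims$top_height - g$junction_z) * 180 / pi
  expect_equal(s$cone_half_angle, chord, tolerance = 1e-9)
  # moving the top rim so the chord is vertical pulls the arc back to ~90
  dims90 <- flask_dimensions(top_diameter = 81.6 - 1e-5, top_height = 99)
  s90 <- solve_smooth_transition(dims90)
  expect_lt(abs(s90$torus_arc_angle - 90), 0.5)
})

test_that("smooth wall is differentiable at the junction, sharp is not", {
  eps <- 1e-4
  slope_jump <- function(geom) {
    zj <- geom$junction_z
    lo <- (wall_radius_at_height(geom, zj) -
             wall_radius_at_height(geom, zj - eps)) / eps
    hi <- (wall_radius_at_height(geom, zj + eps) -
             wall_radius_at_height(geom, zj)) / eps
    abs(hi - lo)
  }
  expect_lt(slope_jump(geom_smooth), 1e-3)   # finite-difference noise only
  expect_gt(slope_jump(geom_sharp), 0.1)
})

test_that("wall radius reproduces the printed dimensions", {
  for (g in list(geom_smooth, geom_sharp)) {
    expect_equal(wall_radius_at_height(g, 0), 26.3, tolerance = 1e-9)
    expect_equal(wall_radius_at_height(g, 99), 15.35, tolerance = 1e-9)
  }
  expect_equal(wall_radius_at_height(geom_sharp, 14.5), 40.8,
               tolerance = 1e-9)
  # variants coincide on the shared quarter-torus, diverge between the
  # sharp junction and the smooth junction height
  z <- seq(0, 14.5, by = 0.5)
  expect_equal(wall_radius_at_height(geom_smooth, z),
               wall_radius_at_height(geom_sharp, z), tolerance = 1e-12)
  z_mid <- (14.5 + geom_smooth$junction_z) / 2
  expect_gt(abs(wall_radius_at_height(geom_smooth, z_mid) -
                  wall_radius_at_height(geom_sharp, z_mid)), 1e-3)
  expect_error(wall_radius_at_height(geom_smooth, 120), "outside")
  expect_error(wall_radius_at_height(geom_smooth, -1), "outside")
})

test_that("enclosed flask volume matches a Monte-Carlo point-in-solid oracle", {
  set.seed(42)
  heights <- stats::runif(5, 5, 95)
  for (zt in heights) {
    v_mc <- mc_inner_volume(geom_smooth, zt, n = 4e6)
    v_q <- inner_volume_below_height(geom_smooth, zt)
    expect_equal(v_q, v_mc, tolerance = 0.002)
  }
})

test_that("flask volume is zero at the bottom and monotone in height", {
  expect_equal(inner_volume_below_height(geom_sharp, 0), 0)
  z <- c(2, 10, 14.5, 20, 50, 99)
  v <- inner_volume_below_height(geom_sharp, z)
  expect_true(all(diff(v) > 0))
})

test_that("wall normals point inward and reflect the transition type", {
  # quarter-torus end (max diameter): normal is horizontal toward the axis
  wp <- wall_point_and_normal(geom_sharp, 14.5, 0)
  expect_equal(as.numeric(wp$normal), c(-1, 0, 0), tolerance = 1e-9)
  # bottom rim: wall tangent to the flat bottom, normal points straight up
  wp <- wall_point_and_normal(geom_sharp, 0, 90)
  expect_equal(as.numeric(wp$normal), c(0, 0, 1), tolerance = 1e-9)
  # cone region: normal tilts down by the half-angle
  a <- geom_sharp$cone_half_angle * pi / 180
  wp <- wall_point_and_normal(geom_sharp, 60, 0)
  expect_equal(as.numeric(wp$normal), c(-cos(a), 0, -sin(a)),
               tolerance = 1e-9)
  # sharp: normals jump across the junction; smooth: continuous
  eps <- 1e-3
  jump <- function(geom) {
    lo <- wall_point_and_normal(geom, geom$junction_z - eps, 0)$normal
    hi <- wall_point_and_normal(geom, geom$junction_z + eps, 0)$normal
    max(abs(hi - lo))
  }
  expect_gt(jump(geom_sharp), 0.04)
  expect_lt(jump(geom_smooth), 1e-3)
})

test_that("geometry export round-trips dims and angles through JSON", {
  js <- geometry_json(geom_smooth)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$torus_arc_angle_deg, geom_smooth$torus_arc_angle)
  expect_equal(parsed$dims$max_diameter, 81.6)
  f <- tempfile(fileext = ".vtk")
  write_geometry_vtk(geom_smooth, f, n_z = 20, n_az = 12)
  v <- read_vtk(f)
  expect_equal(nrow(v$centers), 20 * 12)
  expect_equal(max(v$centers[, 3]), 99)
})
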