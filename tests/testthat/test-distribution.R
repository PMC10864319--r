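test_that("enclosed volume reduces to the flat-surface limit at zero curvature", {
  for (h in c(8, 14.5, 30)) {
    par <- paraboloid_surface(z0 = h, curvature = 0, axis_offset = 12.5)
    expect_equal(enclosed_volume(geom_smooth, par),
                 inner_volume_below_height(geom_smooth, h),
                 tolerance = 1e-3)
  }
  # surface entirely below the flask: nothing enclosed
  par <- paraboloid_surface(z0 = -200, curvature = 0.035, axis_offset = 12.5)
  expect_equal(enclosed_volume(geom_smooth, par), 0)
})

test_that("enclosed volume matches a Monte-Carlo point-in-liquid oracle", {
  set.seed(7)
  cases <- list(c(curv = 0.035, z0 = -30), c(curv = 0.01, z0 = 2))
  for (cs in cases) {
    par <- paraboloid_surface(z0 = cs["z0"], curvature = cs["curv"],
                              axis_offset = 12.5)
    v_mc <- mc_enclosed_volume(geom_smooth, par, n = 4e6)
    expect_equal(enclosed_volume(geom_smooth, par), v_mc, tolerance = 0.005)
  }
})

test_that("volume matching hits the requested filling volume", {
  fit <- fit_ref()
  expect_equal(fit$achieved_volume_mL, 40, tolerance = 1e-3)
  # round trip through the public volume integral
  expect_equal(enclosed_volume(fit$geometry, fit$paraboloid), 40,
               tolerance = 1e-3)
  # an impossible fill names the limit
  expect_error(solve_fill(geom_smooth,
                          operating_condition(n_rpm = 250, d0_cm = 2.5,
                                              V_L_mL = 500)),
               "overflow")
})

test_that("reference conditions reproduce the known maximal liquid height", {
  fit <- fit_ref()
  expect_equal(fit$max_height, 42, tolerance = 1 / 42)
  expect_equal(fit$max_height_azimuth, 180, tolerance = 1e-6)
})

test_that("the inviscid contact line is symmetric about the centrifugal direction", {
  first <- fit_ref()$contact_line
  first <- first[first$crossing == 1L, ]
  h <- first$height[match(0:359, first$azimuth)]
  d <- 1:90
  asym <- abs(h[180 - d + 1] - h[(180 + d) %% 360 + 1])
  expect_lt(max(asym, na.rm = TRUE), 1e-6)
})

test_that("the flat limit recovers the static fill height at every azimuth", {
  fit0 <- solve_fill(geom_smooth,
                     operating_condition(n_rpm = 0, d0_cm = 2.5,
                                         V_L_mL = 40))
  static <- stats::uniroot(function(z)
    inner_volume_below_height(geom_smooth, z) - 40, c(0, 99),
    tol = 1e-9)$root
  h <- fit0$contact_line$height
  expect_equal(h, rep(static, length(h)), tolerance = 1e-4)
})

test_that("maximal height grows with shaking frequency and filling volume", {
  hmax <- function(n, v)
    solve_fill(geom_smooth, operating_condition(n_rpm = n, d0_cm = 2.5,
                                                V_L_mL = v))$max_height
  by_n <- vapply(c(150, 250, 350), hmax, numeric(1), v = 25)
  expect_true(all(diff(by_n) > 0))
  expect_lt(hmax(250, 25), hmax(250, 40))
})

test_that("the sharp transition imprints a kink on the contact line", {
  cond <- cond_ref
  slope_jump_at <- function(fit, zc, bracket) {
    azs <- stats::uniroot(function(a) predict(fit, a) - zc, bracket,
                          tol = 1e-6)$root
    e <- 0.05
    left <- (predict(fit, azs) - predict(fit, azs - e)) / e
    right <- (predict(fit, azs + e) - predict(fit, azs)) / e
    abs(right - left)
  }
  fit_sharp <- solve_fill(geom_sharp, cond)
  first <- fit_sharp$contact_line[fit_sharp$contact_line$crossing == 1L, ]
  iz <- which(diff(sign(first$height - 14.5)) != 0)[1]
  braz <- first$azimuth[c(iz, iz + 1L)]
  expect_gt(slope_jump_at(fit_sharp, 14.5, braz + c(-1, 1)), 0.05)
  # the smooth wall leaves no kink at its own junction height
  fit_sm <- fit_ref()
  first <- fit_sm$contact_line[fit_sm$contact_line$crossing == 1L, ]
  zj <- geom_smooth$junction_z
  iz <- which(diff(sign(first$height - zj)) != 0)[1]
  braz <- first$azimuth[c(iz, iz + 1L)]
  expect_lt(slope_jump_at(fit_sm, zj, braz + c(-1, 1)), 0.01)
})

test_that("strong shaking dries part of the wall and doubles the crossings", {
  fit <- solve_fill(geom_sharp,
                    operating_condition(n_rpm = 450, d0_cm = 2.5,
                                        V_L_mL = 15))
  cl <- fit$contact_line
  n_cross <- tapply(cl$crossing, cl$azimuth, max)
  expect_gt(sum(n_cross >= 2), 0)
  # crossings alternate in direction and descend strictly in height
  for (a in as.numeric(names(n_cross)[n_cross >= 2])[1:5]) {
    sub <- cl[cl$azimuth == a, ]
    expect_true(all(diff(sub$height) < 0))
    expect_equal(sub$direction,
                 rep(c("air_to_water", "water_to_air"),
                     length.out = nrow(sub)))
  }
  # independent dense occupancy scan at one doubled azimuth
  a <- as.numeric(names(n_cross)[n_cross >= 2])[1]
  zz <- seq(0, 99, by = 0.01)
  r <- wall_radius_at_height(geom_sharp, zz)
  th <- a * pi / 180
  par <- fit$paraboloid
  wet <- (par$z0 + par$curvature *
            (r^2 + par$axis_offset^2 -
               2 * r * par$axis_offset * cos(th))) >= zz
  expect_equal(sum(diff(wet) != 0), max(cl$crossing[cl$azimuth == a]))
})

test_that("contact lines re-sample consistently and round-trip to disk", {
  fit <- fit_ref()
  cl5 <- contact_line_of(fit, azimuth_step = 5)
  expect_equal(attr(cl5, "max_height"), fit$max_height, tolerance = 1e-6)
  sub <- cl5[cl5$crossing == 1L & cl5$azimuth %% 5 == 0, ]
  full <- fit$contact_line[fit$contact_line$crossing == 1L, ]
  common <- intersect(sub$azimuth, full$azimuth)
  expect_equal(sub$height[match(common, sub$azimuth)],
               full$height[match(common, full$azimuth)], tolerance = 1e-9)
  f <- tempfile(fileext = ".tsv")
  write_contact_line(fit$contact_line, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(fit$contact_line))
  expect_equal(max(tab$height_mm), fit$max_height, tolerance = 1e-6)
})
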