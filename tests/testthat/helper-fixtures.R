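# Shared fixtures and independent oracles. Geometries and the reference
# mechanistic fit are built once per test run; Monte-Carlo oracles are
# chunked rejection samplers, independent of the quadrature code they
# check.

geom_smooth <- flask_geometry(transition = "smooth")
geom_sharp <- flask_geometry(transition = "sharp")
cond_ref <- operating_condition(n_rpm = 250, d0_cm = 2.5, V_L_mL = 40)
water_ref <- fluid_properties(viscosity = 0.89e-3)
visc_ref <- fluid_properties(viscosity = 16.7e-3)

# cached reference fit (40 mL, 250 rpm, smooth geometry)
fit_ref_cache <- new.env()
fit_ref <- function() {
  if (is.null(fit_ref_cache$fit))
    fit_ref_cache$fit <- solve_fill(geom_smooth, cond_ref)
  fit_ref_cache$fit
}

# Monte-Carlo point-in-solid volume below height z_top (mL), by rejection
# sampling in the bounding box.
mc_inner_volume <- function(geom, z_top, n = 4e6, chunk = 1e6) {
  r_max <- geom$centre_radius + geom$dims$torus_radius
  hits <- 0
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    x <- stats::runif(m, -r_max, r_max)
    y <- stats::runif(m, -r_max, r_max)
    z <- stats::runif(m, 0, z_top)
    rho <- sqrt(x^2 + y^2)
    hits <- hits + sum(rho <= wall_radius_at_height(geom, z))
    done <- done + m
  }
  (hits / n) * (2 * r_max)^2 * z_top / 1000
}

# Monte-Carlo point-in-liquid volume (mL) for a paraboloid surface.
mc_enclosed_volume <- function(geom, par, n = 4e6, chunk = 1e6) {
  r_max <- geom$centre_radius + geom$dims$torus_radius
  top <- geom$dims$top_height
  z_top <- min(top, max(1, par$z0 + par$curvature *
                          (par$axis_offset + r_max)^2))
  hits <- 0
  done <- 0
  while (done < n) {
    m <- min(chunk, n - done)
    x <- stats::runif(m, -r_max, r_max)
    y <- stats::runif(m, -r_max, r_max)
    z <- stats::runif(m, 0, z_top)
    rho <- sqrt(x^2 + y^2)
    th <- atan2(y, x)
    inside <- rho <= wall_radius_at_height(geom, z) &
      z <= par$z0 + par$curvature *
        (rho^2 + par$axis_offset^2 -
           2 * rho * par$axis_offset * cos(th - par$axis_azimuth * pi / 180))
    hits <- hits + sum(inside)
    done <- done + m
  }
  (hits / n) * (2 * r_max)^2 * z_top / 1000
}

# Analytic topmost surface/wall-probe crossing for a rotated paraboloid
# bulk, along the probe line at one azimuth and wall-normal offset. Fine
# scan plus linear interpolation; independent of the threshold-crossing
# extraction it serves as oracle for.
probe_crossing_oracle <- function(geom, par, delta_deg, az_deg, offset_mm,
                                  dz = 0.005) {
  zz <- seq(0, geom$dims$top_height, by = dz)
  wp <- wall_point_and_normal(geom, zz, az_deg)
  px <- wp$point[, 1] + offset_mm * wp$normal[, 1]
  py <- wp$point[, 2] + offset_mm * wp$normal[, 2]
  pz <- wp$point[, 3] + offset_mm * wp$normal[, 3]
  rho <- sqrt(px^2 + py^2)
  th <- atan2(py, px) - delta_deg * pi / 180
  h <- par$z0 + par$curvature *
    (rho^2 + par$axis_offset^2 - 2 * rho * par$axis_offset * cos(th))
  g <- h - pz
  s <- which(g[-1] * g[-length(g)] <= 0)
  if (!length(s)) return(NA_real_)
  j <- max(s)
  zz[j] + dz * g[j] / (g[j] - g[j + 1])
}
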