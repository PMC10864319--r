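#' Centrifugal paraboloid surface
#'
#' Free surface of an inviscid liquid rotating about the shaker axis: height
#' `h(s) = z0 + c * s^2`, with `s` the horizontal distance from the shaker
#' rotation axis and `c = w^2 / (2 g)`. The axis sits at horizontal distance
#' `axis_offset` (= d0/2) from the flask axis, at azimuth `axis_azimuth`
#' (0 degrees by convention, so the centrifugal direction is 180 degrees).
#'
#' @param z0 apex height (mm)
#' @param curvature `c = w^2 / (2 g)` in 1/mm
#' @param axis_offset horizontal shaker-axis offset, mm
#' @param axis_azimuth azimuth of the shaker axis, degrees
#' @return object of class `paraboloid_surface`
#' @export
paraboloid_surface <- function(z0, curvature, axis_offset,
                               axis_azimuth = 0) {
  if (curvature < 0) stop("curvature must be >= 0")
  if (axis_offset < 0) stop("axis offset must be >= 0")
  structure(list(z0 = z0, curvature = curvature,
                 axis_offset = axis_offset, axis_azimuth = axis_azimuth),
            class = "paraboloid_surface")
}

# Paraboloid curvature (1/mm) from an operating condition; g in m/s^2.
paraboloid_curvature <- function(cond, g = 9.81) {
  w <- angular_velocity(cond)
  w^2 / (2 * g * 1000)  # g in mm/s^2 -> curvature per mm
}

# Surface height (mm) above plan point(s) given in flask polar coordinates.
paraboloid_height <- function(par, rho, theta_rad) {
  off <- par$axis_offset
  a0 <- par$axis_azimuth * pi / 180
  s2 <- rho^2 + off^2 - 2 * rho * off * cos(theta_rad - a0)
  par$z0 + par$curvature * s2
}

#' Liquid volume enclosed between flask wall and paraboloid
#'
#' Volume of the region inside the wall, above the flat bottom and below
#' the paraboloid surface, by a vectorised midpoint quadrature in plan-view
#' polar coordinates. Columns of liquid between the lower and upper wall
#' branches (under the torus overhang) are handled exactly through the
#' per-radius wall height interval.
#'
#' @param geom a [flask_geometry()] object
#' @param par a [paraboloid_surface()]
#' @param n_r,n_theta quadrature resolution (radial x azimuthal)
#' @return volume in mL
#' @export
enclosed_volume <- function(geom, par, n_r = 800, n_theta = 720) {
  stopifnot(inherits(geom, "flask_geometry"),
            inherits(par, "paraboloid_surface"))
  q <- volume_quadrature_grid(geom, n_r, n_theta)
  enclosed_volume_on_grid(par, q)
}

# Precomputed quadrature grid: everything except the paraboloid height.
volume_quadrature_grid <- function(geom, n_r = 800, n_theta = 720) {
  r_max <- geom$centre_radius + geom$dims$torus_radius
  dr <- r_max / n_r
  dth <- 2 * pi / n_theta
  rho <- (seq_len(n_r) - 0.5) * dr
  th <- (seq_len(n_theta) - 0.5) * dth
  iv <- wall_height_interval(geom, rho)
  list(rho = rho, th = th,
       z_lo = iv$z_lo, z_hi = pmin(iv$z_hi, geom$dims$top_height),
       weight = rho * dr * dth,
       s2_base = outer(rho^2, rep(1, length(th))),
       cos_th = cos(th))
}

enclosed_volume_on_grid <- function(par, q) {
  off <- par$axis_offset
  a0 <- par$axis_azimuth * pi / 180
  s2 <- q$s2_base + off^2 -
    2 * off * outer(q$rho, cos(q$th - a0))
  h <- par$z0 + par$curvature * s2
  depth <- pmax(pmin(h, q$z_hi) - q$z_lo, 0)
  sum(depth * q$weight) / 1000  # mm^3 -> mL
}

#' Fit the mechanistic liquid distribution
#'
#' The simplified inviscid model of the liquid in an orbitally shaken
#' flask: the shaking motion is read as a superposition of a translation
#' and an opposing rotation, so the free surface is a symmetric paraboloid
#' set by the centrifugal field, and the apex height `z0` is adjusted until
#' the volume enclosed between paraboloid and flask wall matches the
#' filling volume. Viscous and capillary forces are entirely neglected;
#' surface tension and contact angle play no role.
#'
#' @param geom a [flask_geometry()] object
#' @param cond an [operating_condition()]
#' @param azimuth_step contact-line azimuth grid (degrees)
#' @param g gravitational acceleration (m/s^2)
#' @param vol_tol relative volume-matching tolerance
#' @param n_r,n_theta quadrature resolution passed to the volume integral
#' @return an object of class `liquid_distribution`: the solved paraboloid,
#'   the per-azimuth contact line, the maximal contact height and its
#'   azimuth, and the achieved volume
#' @export
#' @examples
#' \donttest{
#' geom <- flask_geometry(transition = "smooth")
#' cond <- operating_condition(n_rpm = 250, d0_cm = 2.5, V_L_mL = 40)
#' fit <- solve_fill(geom, cond)
#' fit$max_height   # about 42 mm
#' }
solve_fill <- function(geom, cond, azimuth_step = 1, g = 9.81,
                       vol_tol = 1e-3, n_r = 800, n_theta = 720) {
  stopifnot(inherits(geom, "flask_geometry"),
            inherits(cond, "operating_condition"))
  V_target <- cond$V_L * 1e6  # mL
  cc <- paraboloid_curvature(cond, g)
  off <- cond$d0 / 2 * 1000   # mm
  q <- volume_quadrature_grid(geom, n_r, n_theta)
  r_max <- geom$centre_radius + geom$dims$torus_radius
  top <- geom$dims$top_height

  vol_at <- function(z0)
    enclosed_volume_on_grid(paraboloid_surface(z0, cc, off), q)

  z0_lo <- -cc * (off + r_max)^2
  v_hi <- vol_at(top)
  if (V_target > v_hi)
    stop(sprintf(paste0("filling volume %.3g mL exceeds the %.3g mL the ",
                        "modelled flask can hold at this shaking frequency ",
                        "(liquid would overflow the %.3g mm wall)"),
                 V_target, v_hi, top))
  root <- stats::uniroot(function(z0) vol_at(z0) - V_target,
                         c(z0_lo, top), tol = 1e-7)
  z0 <- root$root
  v_ach <- vol_at(z0)
  if (abs(v_ach - V_target) > vol_tol * V_target)
    stop("volume matching failed to reach the requested tolerance")
  par <- paraboloid_surface(z0, cc, off)

  cl <- wall_crossings(geom, par, azimuth_step)
  first <- cl[cl$crossing == 1L, ]
  apex <- apex_from_line(first$azimuth, first$height)

  structure(list(geometry = geom, cond = cond, paraboloid = par,
                 contact_line = cl,
                 max_height = apex$height,
                 max_height_azimuth = apex$azimuth,
                 achieved_volume_mL = v_ach,
                 azimuth_step = azimuth_step),
            class = "liquid_distribution")
}

# All heights at which the paraboloid surface crosses the wall, per azimuth.
# g(z) = surface height above the wall point minus z changes sign at a
# crossing; crossings are refined by uniroot and returned descending from
# the top (crossing 1 is the contact height).
wall_crossings <- function(geom, par, azimuth_step = 1, z_scan = 0.05) {
  top <- geom$dims$top_height
  az <- seq(0, 360 - azimuth_step, by = azimuth_step)
  zz <- seq(0, top, by = z_scan)
  r <- wall_radius_at_height(geom, zz)
  res <- vector("list", length(az))
  for (i in seq_along(az)) {
    th <- az[i] * pi / 180
    gv <- paraboloid_height(par, r, th) - zz
    sgn <- sign(gv)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
    if (!length(idx)) { res[[i]] <- NULL; next }
    gfun <- function(z) {
      rw <- wall_radius_at_height(geom, z)
      paraboloid_height(par, rw, th) - z
    }
    hts <- vapply(idx, function(j) {
      if (gv[j] == 0) return(zz[j])
      stats::uniroot(gfun, c(zz[j], zz[j + 1L]), tol = 1e-8)$root
    }, numeric(1))
    hts <- sort(unique(hts), decreasing = TRUE)
    dir <- ifelse(seq_along(hts) %% 2L == 1L, "air_to_water", "water_to_air")
    res[[i]] <- data.frame(azimuth = az[i], crossing = seq_along(hts),
                           height = hts, direction = dir)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Apex (maximal height) azimuth; ties resolved by circular mean.
apex_from_line <- function(az, h, tie_tol = 1e-9) {
  hmax <- max(h)
  tie <- az[h >= hmax - tie_tol]
  a <- tie * pi / 180
  mean_az <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  list(height = hmax, azimuth = (mean_az + 360) %% 360)
}

#' Contact line of a solved liquid distribution
#'
#' Re-samples the wall crossings of the fitted paraboloid on a new azimuth
#' grid. For strongly curved surfaces a single azimuth can hold several
#' crossings (the bottom centre is dry and the surface re-enters).
#'
#' @param dist a [solve_fill()] result
#' @param azimuth_step degrees
#' @return data.frame with `azimuth`, `crossing`, `height`, `direction`,
#'   carrying the apex as attributes `max_height`, `max_height_azimuth`
#' @export
contact_line_of <- function(dist, azimuth_step = 1) {
  stopifnot(inherits(dist, "liquid_distribution"))
  cl <- wall_crossings(dist$geometry, dist$paraboloid, azimuth_step)
  first <- cl[cl$crossing == 1L, ]
  apex <- apex_from_line(first$azimuth, first$height)
  attr(cl, "max_height") <- apex$height
  attr(cl, "max_height_azimuth") <- apex$azimuth
  cl
}

#' @export
print.liquid_distribution <- function(x, ...) {
  cat("Inviscid mechanistic liquid distribution\n")
  print(x$cond)
  cat(sprintf("  paraboloid: z0 = %.2f mm, curvature = %.4g 1/mm, offset = %.1f mm\n",
              x$paraboloid$z0, x$paraboloid$curvature,
              x$paraboloid$axis_offset))
  cat(sprintf("  matched volume: %.3f mL\n", x$achieved_volume_mL))
  cat(sprintf("  max contact height: %.2f mm at azimuth %.1f deg\n",
              x$max_height, x$max_height_azimuth))
  invisible(x)
}

#' @export
summary.liquid_distribution <- function(object, ...) {
  first <- object$contact_line[object$contact_line$crossing == 1L, ]
  out <- list(max_height = object$max_height,
              max_height_azimuth = object$max_height_azimuth,
              min_height = min(first$height),
              wetted_azimuths = nrow(first),
              azimuth_step = object$azimuth_step,
              achieved_volume_mL = object$achieved_volume_mL,
              z0 = object$paraboloid$z0,
              curvature = object$paraboloid$curvature)
  class(out) <- "summary.liquid_distribution"
  out
}

#' @export
print.summary.liquid_distribution <- function(x, ...) {
  cat(sprintf("max contact height %.2f mm at %.1f deg; min %.2f mm\n",
              x$max_height, x$max_height_azimuth, x$min_height))
  cat(sprintf("%d wetted azimuths (step %g deg); volume %.3f mL; z0 %.2f mm\n",
              x$wetted_azimuths, x$azimuth_step, x$achieved_volume_mL, x$z0))
  invisible(x)
}

#' Predict contact heights at arbitrary azimuths
#'
#' @param object a [solve_fill()] result
#' @param azimuth azimuths in degrees; defaults to the fitted grid
#' @param ... unused
#' @return numeric vector of first (topmost) contact heights, NA where the
#'   wall is dry
#' @export
predict.liquid_distribution <- function(object, azimuth = NULL, ...) {
  if (is.null(azimuth)) {
    first <- object$contact_line[object$contact_line$crossing == 1L, ]
    out <- rep(NA_real_, 360 / object$azimuth_step)
    names(out) <- seq(0, 360 - object$azimuth_step, by = object$azimuth_step)
    out[as.character(first$azimuth)] <- first$height
    return(out)
  }
  vapply(azimuth %% 360, function(a) {
    cl <- wall_crossings_single(object$geometry, object$paraboloid, a)
    if (length(cl)) max(cl) else NA_real_
  }, numeric(1))
}

wall_crossings_single <- function(geom, par, az, z_scan = 0.05) {
  top <- geom$dims$top_height
  zz <- seq(0, top, by = z_scan)
  r <- wall_radius_at_height(geom, zz)
  th <- az * pi / 180
  gv <- paraboloid_height(par, r, th) - zz
  sgn <- sign(gv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0 | sgn[-length(sgn)] == 0)
  if (!length(idx)) return(numeric(0))
  gfun <- function(z) {
    rw <- wall_radius_at_height(geom, z)
    paraboloid_height(par, rw, th) - z
  }
  vapply(idx, function(j) {
    if (gv[j] == 0) return(zz[j])
    stats::uniroot(gfun, c(zz[j], zz[j + 1L]), tol = 1e-8)$root
  }, numeric(1))
}

#' Plot a contact line over azimuth
#'
#' Height of the liquid contact line over one rotation, viewed from the
#' centre of the flask; the centrifugal direction (azimuth 180) is marked.
#'
#' @param x a [solve_fill()] result
#' @param ... passed to [graphics::plot()]
#' @export
plot.liquid_distribution <- function(x, ...) {
  first <- x$contact_line[x$contact_line$crossing == 1L, ]
  graphics::plot(first$azimuth, first$height, type = "l",
                 xlab = "azimuth (deg)", ylab = "contact height (mm)",
                 xlim = c(0, 360), ...)
  graphics::abline(v = 180, lty = 2)
  invisible(x)
}

#' Write a contact line as delimited text
#'
#' Tab-separated columns azimuth_deg, crossing_index, height_mm (and
#' direction where present).
#'
#' @param cl contact-line data.frame ([contact_line_of()] or the
#'   `contact_line` element of a fit)
#' @param file output path
#' @return the path, invisibly
#' @export
write_contact_line <- function(cl, file) {
  out <- data.frame(azimuth_deg = cl$azimuth,
                    crossing_index = cl$crossing,
                    height_mm = cl$height)
  if (!is.null(cl$direction)) out$direction <- cl$direction
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
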