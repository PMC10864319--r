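#' Inner dimensions of a conical shake flask
#'
#' Collects the printed inner dimensions of a 250 mL Erlenmeyer-type shake
#' flask. The lower wall is a partial torus of tube radius `torus_radius`
#' whose centre circle sits at `max_diameter/2 - torus_radius` from the flask
#' axis at height `height_of_max_diameter`; the upper wall is a cone tapering
#' to `top_diameter` at `top_height`. The bottom is modelled flat with
#' diameter `bottom_diameter = max_diameter - 2 * torus_radius`.
#'
#' Defaults are the milled-flask mean dimensions of an unbaffled 250 mL
#' flask: torus radius 14.5 mm, maximal diameter 81.6 mm at 14.5 mm height,
#' tapering to 30.7 mm at 99 mm, flat bottom 52.6 mm.
#'
#' @param torus_radius tube radius of the lower torus segment (mm)
#' @param max_diameter maximal inner diameter (mm)
#' @param height_of_max_diameter height of the maximal diameter (mm)
#' @param top_diameter inner diameter at the top of the modelled wall (mm)
#' @param top_height height of the top rim (mm)
#' @param bottom_diameter flat-bottom diameter (mm); must equal
#'   `max_diameter - 2 * torus_radius` for a consistent torus construction
#' @return an object of class `flask_dimensions`
#' @export
#' @examples
#' flask_dimensions()
flask_dimensions <- function(torus_radius = 14.5,
                             max_diameter = 81.6,
                             height_of_max_diameter = 14.5,
                             top_diameter = 30.7,
                             top_height = 99,
                             bottom_diameter = max_diameter - 2 * torus_radius) {
  d <- list(torus_radius = torus_radius,
            max_diameter = max_diameter,
            height_of_max_diameter = height_of_max_diameter,
            top_diameter = top_diameter,
            top_height = top_height,
            bottom_diameter = bottom_diameter)
  for (nm in names(d)) {
    if (!is.numeric(d[[nm]]) || length(d[[nm]]) != 1L || !is.finite(d[[nm]]) ||
        d[[nm]] <= 0)
      stop("flask dimension '", nm, "' must be a single positive number")
  }
  if (max_diameter <= top_diameter)
    stop("max_diameter must exceed top_diameter")
  if (top_height <= height_of_max_diameter)
    stop("top_height must exceed height_of_max_diameter")
  if (abs(bottom_diameter - (max_diameter - 2 * torus_radius)) > 1e-9)
    stop("bottom_diameter must equal max_diameter - 2*torus_radius ",
         "(torus construction consistency)")
  structure(d, class = "flask_dimensions")
}

#' Cone half-angle from the printed rim circles
#'
#' Half-angle of the upper cone, measured from the vertical, from the radial
#' taper between the maximal-diameter circle and the top rim circle. For the
#' default dimensions this evaluates to 16.76 degrees.
#'
#' @param dims a [flask_dimensions()] object
#' @return angle in degrees
#' @export
cone_half_angle_from_dims <- function(dims) {
  stopifnot(inherits(dims, "flask_dimensions"))
  dz <- dims$top_height - dims$height_of_max_diameter
  if (dz <= 0) stop("degenerate dimensions: rim circles at equal heights")
  dr <- dims$max_diameter / 2 - dims$top_diameter / 2
  atan2(dr, dz) * 180 / pi
}

#' Solve the tangency-smoothed torus-cone transition
#'
#' Extends the lower torus past a quarter turn until its wall tangent is
#' collinear with the chord from the torus end point to the fixed top rim
#' (`top_diameter/2` at `top_height`). The torus arc angle is measured from
#' the flat bottom rim (0 degrees) so a quarter torus ends at 90 degrees;
#' for the default dimensions the tangency arc angle is 107.2 degrees. The
#' cone half-angle is recomputed from the solved chord and therefore differs
#' slightly from [cone_half_angle_from_dims()].
#'
#' @param dims a [flask_dimensions()] object
#' @param tol root tolerance on the arc angle (degrees)
#' @return list with `torus_arc_angle` and `cone_half_angle`, both degrees
#' @export
solve_smooth_transition <- function(dims, tol = 1e-4) {
  stopifnot(inherits(dims, "flask_dimensions"))
  rt <- dims$torus_radius
  Rc <- dims$max_diameter / 2 - rt
  top_r <- dims$top_diameter / 2
  top_z <- dims$top_height
  # tangent at arc angle phi is (cos phi, sin phi) in the (r, z) plane;
  # tangency <=> cross product with the chord to the top rim vanishes
  resid <- function(phi_deg) {
    p <- phi_deg * pi / 180
    r <- Rc + rt * sin(p)
    z <- rt * (1 - cos(p))
    (top_r - r) * sin(p) - (top_z - z) * cos(p)
  }
  lo <- 90 + 1e-9
  hi <- 180 - 1e-6
  if (resid(lo) * resid(hi) > 0)
    stop("no tangency solution with arc angle in (90, 180) degrees")
  phi <- stats::uniroot(resid, c(lo, hi), tol = tol)$root
  p <- phi * pi / 180
  r_j <- Rc + rt * sin(p)
  z_j <- rt * (1 - cos(p))
  half <- atan2(r_j - top_r, top_z - z_j) * 180 / pi
  list(torus_arc_angle = phi, cone_half_angle = half)
}

#' Parametric shake-flask wall geometry
#'
#' Builds the piecewise torus-plus-cone model of the inner flask wall in one
#' of two variants. `"sharp"` uses a quarter torus (arc angle exactly 90
#' degrees) with the cone from [cone_half_angle_from_dims()] attached at the
#' maximal diameter, which leaves a slope discontinuity at the junction.
#' `"smooth"` extends the torus to the tangency angle from
#' [solve_smooth_transition()], producing a continuously differentiable wall
#' that follows real flask glassware much more closely.
#'
#' @param dims a [flask_dimensions()] object
#' @param transition `"smooth"` or `"sharp"`
#' @return an object of class `flask_geometry` with the solved junction
#'   point, arc angle and cone half-angle
#' @export
#' @examples
#' geom <- flask_geometry(transition = "smooth")
#' geom$torus_arc_angle   # 107.2 degrees for the default dimensions
flask_geometry <- function(dims = flask_dimensions(),
                           transition = c("smooth", "sharp")) {
  transition <- match.arg(transition)
  stopifnot(inherits(dims, "flask_dimensions"))
  rt <- dims$torus_radius
  Rc <- dims$max_diameter / 2 - rt
  if (transition == "sharp") {
    arc <- 90
    half <- cone_half_angle_from_dims(dims)
  } else {
    s <- solve_smooth_transition(dims)
    arc <- s$torus_arc_angle
    half <- s$cone_half_angle
  }
  p <- arc * pi / 180
  g <- list(dims = dims,
            transition = transition,
            torus_arc_angle = arc,
            cone_half_angle = half,
            centre_radius = Rc,
            junction_r = Rc + rt * sin(p),
            junction_z = rt * (1 - cos(p)))
  structure(g, class = "flask_geometry")
}

#' @export
print.flask_geometry <- function(x, ...) {
  d <- x$dims
  cat("Shake flask geometry (", x$transition, " torus-cone transition)\n",
      sep = "")
  cat(sprintf("  torus radius %.1f mm, max diameter %.1f mm at %.1f mm\n",
              d$torus_radius, d$max_diameter, d$height_of_max_diameter))
  cat(sprintf("  top rim %.1f mm at %.1f mm, flat bottom %.1f mm\n",
              d$top_diameter, d$top_height, d$bottom_diameter))
  cat(sprintf("  torus arc angle %.2f deg, cone half-angle %.2f deg\n",
              x$torus_arc_angle, x$cone_half_angle))
  invisible(x)
}

#' Inner wall radius at a given height
#'
#' Evaluates the single-valued wall profile r(z): the torus arc up to the
#' junction height, the cone above it. Continuous everywhere; differentiable
#' at the junction only for the smooth variant.
#'
#' @param geom a [flask_geometry()] object
#' @param z heights (mm), each in `[0, top_height]`; vectorised
#' @return wall radii (mm)
#' @export
wall_radius_at_height <- function(geom, z) {
  stopifnot(inherits(geom, "flask_geometry"))
  d <- geom$dims
  if (any(z < -1e-9 | z > d$top_height + 1e-9))
    stop("height outside [0, ", d$top_height, "] mm")
  z <- pmin(pmax(z, 0), d$top_height)
  rt <- d$torus_radius
  r <- numeric(length(z))
  on_torus <- z <= geom$junction_z + 1e-9
  if (any(on_torus)) {
    phi <- acos(pmin(pmax(1 - z[on_torus] / rt, -1), 1))
    r[on_torus] <- geom$centre_radius + rt * sin(phi)
  }
  if (any(!on_torus)) {
    tanh_ <- tan(geom$cone_half_angle * pi / 180)
    r[!on_torus] <- geom$junction_r - (z[!on_torus] - geom$junction_z) * tanh_
  }
  r
}

# Height interval [z_lo, z_hi] over which a plan-view radius rho lies inside
# the wall. Vectorised over rho; radii beyond the maximal radius get an
# empty interval (z_lo > z_hi). Used by the liquid-volume quadratures.
wall_height_interval <- function(geom, rho) {
  d <- geom$dims
  rt <- d$torus_radius
  Rc <- geom$centre_radius
  r_max <- Rc + rt
  top_r <- d$top_diameter / 2
  tanh_ <- tan(geom$cone_half_angle * pi / 180)

  z_lo <- numeric(length(rho))
  above <- rho > Rc
  s <- pmin((rho[above] - Rc) / rt, 1)
  z_lo[above] <- rt * (1 - cos(asin(s)))

  z_hi <- rep(d$top_height, length(rho))
  # upper torus branch exists only when the arc passes 90 degrees
  on_ut <- rho > geom$junction_r & rho <= r_max
  if (any(on_ut)) {
    s <- pmin((rho[on_ut] - Rc) / rt, 1)
    z_hi[on_ut] <- rt * (1 - cos(pi - asin(s)))
  }
  on_cone <- rho >= top_r & rho <= geom$junction_r
  z_hi[on_cone] <- geom$junction_z + (geom$junction_r - rho[on_cone]) / tanh_

  bad <- rho > r_max
  z_lo[bad] <- 1
  z_hi[bad] <- 0
  list(z_lo = z_lo, z_hi = z_hi)
}

#' Flask volume below a height
#'
#' Volume enclosed by the inner wall and the flat bottom up to height `z`,
#' by adaptive quadrature of `pi * r(z')^2` split at the torus-cone
#' junction. Absolute tolerance 1e-4 mL.
#'
#' @param geom a [flask_geometry()] object
#' @param z height (mm), in `[0, top_height]`; vectorised
#' @return volume in mL (1 mL = 1000 mm^3)
#' @export
inner_volume_below_height <- function(geom, z) {
  stopifnot(inherits(geom, "flask_geometry"))
  d <- geom$dims
  if (any(z < -1e-9 | z > d$top_height + 1e-9))
    stop("height outside [0, ", d$top_height, "] mm")
  f <- function(zz) pi * wall_radius_at_height(geom, zz)^2
  one <- function(zt) {
    if (zt <= 0) return(0)
    brk <- sort(unique(pmin(c(geom$junction_z, zt), zt)))
    brk <- c(0, brk[brk > 0])
    v <- 0
    for (i in seq_len(length(brk) - 1L)) {
      v <- v + stats::integrate(f, brk[i], brk[i + 1L],
                                abs.tol = 0.05, rel.tol = 1e-8)$value
    }
    v / 1000  # mm^3 -> mL
  }
  vapply(z, one, numeric(1))
}

#' Wall point and inward normal
#'
#' Point on the inner wall surface at height `z` and azimuth `az`, together
#' with the inward-pointing unit normal, in flask-fixed coordinates (z up,
#' azimuth 0 on the +x axis, degrees increasing counter-clockwise). The
#' centrifugal direction is conventionally plotted at azimuth 180.
#'
#' @param geom a [flask_geometry()] object
#' @param z heights (mm); vectorised together with `az`
#' @param az azimuths (degrees in `[0, 360)`)
#' @return list with `point` and `normal`, each an n x 3 matrix (mm /
#'   unit vector)
#' @export
wall_point_and_normal <- function(geom, z, az) {
  stopifnot(inherits(geom, "flask_geometry"))
  n <- max(length(z), length(az))
  z <- rep_len(z, n); az <- rep_len(az, n)
  d <- geom$dims
  if (any(z < -1e-9 | z > d$top_height + 1e-9))
    stop("height outside [0, ", d$top_height, "] mm")
  z <- pmin(pmax(z, 0), d$top_height)
  rt <- d$torus_radius
  r <- wall_radius_at_height(geom, z)
  # inward normal in the (radial, vertical) plane
  nr <- numeric(n); nz <- numeric(n)
  on_torus <- z <= geom$junction_z + 1e-9
  phi <- acos(pmin(pmax(1 - z[on_torus] / rt, -1), 1))
  nr[on_torus] <- -sin(phi)
  nz[on_torus] <- cos(phi)
  a <- geom$cone_half_angle * pi / 180
  nr[!on_torus] <- -cos(a)
  nz[!on_torus] <- -sin(a)
  th <- az * pi / 180
  list(point = cbind(x = r * cos(th), y = r * sin(th), z = z),
       normal = cbind(x = nr * cos(th), y = nr * sin(th), z = nz))
}

#' Export the wall surface as a triangulated legacy VTK file
#'
#' Surface of revolution of the wall profile plus the flat bottom, written
#' as ASCII legacy VTK POLYDATA for visualisation.
#'
#' @param geom a [flask_geometry()] object
#' @param file output path
#' @param n_z,n_az profile and azimuthal resolution
#' @return the file path, invisibly
#' @export
write_geometry_vtk <- function(geom, file, n_z = 120, n_az = 90) {
  z <- seq(0, geom$dims$top_height, length.out = n_z)
  r <- wall_radius_at_height(geom, z)
  th <- seq(0, 2 * pi, length.out = n_az + 1L)[-(n_az + 1L)]
  pts <- cbind(as.vector(outer(r, cos(th))),
               as.vector(outer(r, sin(th))),
               rep(z, times = n_az))
  idx <- function(iz, ia) (ia - 1L) * n_z + iz - 1L  # 0-based
  tri <- list()
  for (ia in seq_len(n_az)) {
    ia2 <- if (ia == n_az) 1L else ia + 1L
    iz <- seq_len(n_z - 1L)
    tri[[length(tri) + 1L]] <- cbind(idx(iz, ia), idx(iz + 1L, ia), idx(iz + 1L, ia2))
    tri[[length(tri) + 1L]] <- cbind(idx(iz, ia), idx(iz + 1L, ia2), idx(iz, ia2))
  }
  tri <- do.call(rbind, tri)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "shake flask inner wall surface", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(pts), "double")), con)
  utils::write.table(format(pts, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("POLYGONS", nrow(tri), nrow(tri) * 4L), con)
  utils::write.table(cbind(3L, tri), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Geometry echo as JSON
#'
#' @param geom a [flask_geometry()] object
#' @param file optional output path; when `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to file)
#' @export
geometry_json <- function(geom, file = NULL) {
  out <- list(dims = unclass(geom$dims),
              transition = geom$transition,
              torus_arc_angle_deg = geom$torus_arc_angle,
              cone_half_angle_deg = geom$cone_half_angle,
              junction_r_mm = geom$junction_r,
              junction_z_mm = geom$junction_z)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
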