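#' Volume-fraction field with a point-sampling contract
#'
#' Wraps any function `point (x, y, z) -> alpha` (liquid volume fraction in
#' `[0, 1]`, flask-fixed coordinates in mm) together with the bounding flask
#' geometry. Samples for which the function returns `NA` (outside the
#' field's support) are read as air (`alpha = 0`) and counted.
#'
#' @param fun vectorised function of three coordinate vectors returning
#'   alpha values
#' @param geometry the bounding [flask_geometry()]
#' @param meta optional metadata list (kept as an attribute)
#' @return object of class `alpha_field`
#' @export
alpha_field <- function(fun, geometry, meta = list()) {
  stopifnot(is.function(fun), inherits(geometry, "flask_geometry"))
  structure(list(fun = fun, geometry = geometry, meta = meta),
            class = "alpha_field")
}

#' Extract liquid contact lines from a volume-fraction field
#'
#' Reimplements probe-based contact-line extraction: for every azimuth and
#' every wall-normal offset, the field is sampled on a vertical grid at
#' `wall point + offset * inward normal`, cells with `alpha >= 0.5` are
#' classified as water, and every air/water threshold crossing is recorded
#' descending from the top of the flask. The first air-to-water crossing is
#' the contact height; crossing heights are reported at the midpoint of the
#' bracketing samples. The default grids (0.5 mm in z, 1 degree around the
#' axis) give roughly 72,000 sampled positions per offset for the default
#' 99 mm flask; the default offset ladder starts 50 um inside the wall and
#' grows in 200 um steps to 1050 um, so that a wall film can be skipped by
#' reading the larger offsets.
#'
#' @param field an [alpha_field()]
#' @param z_step vertical sampling distance (mm)
#' @param azimuth_step azimuthal step (degrees)
#' @param offsets_um wall-normal offsets (micrometres), all > 0
#' @param z_max top of the scan (mm); defaults to the flask top height
#' @return object of class `contact_line_set`: the full crossing table, the
#'   per-(azimuth, offset) contact heights, and the sampling metadata
#' @export
extract_contact_lines <- function(field, z_step = 0.5, azimuth_step = 1,
                                  offsets_um = c(50, 250, 450, 650, 850, 1050),
                                  z_max = NULL) {
  stopifnot(inherits(field, "alpha_field"))
  if (any(offsets_um <= 0))
    stop("offsets must be strictly positive (sampling inside the wall)")
  offsets_um <- sort(offsets_um)
  geom <- field$geometry
  if (is.null(z_max)) z_max <- geom$dims$top_height
  zz <- seq(z_max, 0, by = -z_step)      # descending from the top
  az <- seq(0, 360 - azimuth_step, by = azimuth_step)
  nz <- length(zz); na <- length(az)

  wp <- wall_point_and_normal(geom, rep(zz, times = na), rep(az, each = nz))
  n_outside <- 0L
  crossings <- vector("list", length(offsets_um))
  contact <- matrix(NA_real_, nrow = na, ncol = length(offsets_um),
                    dimnames = list(NULL, paste0(offsets_um, "um")))
  for (k in seq_along(offsets_um)) {
    o <- offsets_um[k] / 1000  # mm
    px <- wp$point[, 1] + o * wp$normal[, 1]
    py <- wp$point[, 2] + o * wp$normal[, 2]
    pz <- wp$point[, 3] + o * wp$normal[, 3]
    a <- field$fun(px, py, pz)
    n_outside <- n_outside + sum(is.na(a))
    a[is.na(a)] <- 0
    water <- matrix(a >= 0.5, nrow = nz, ncol = na)
    # changes between consecutive samples, walking downward
    chg <- water[-1, , drop = FALSE] != water[-nz, , drop = FALSE]
    idx <- which(chg, arr.ind = TRUE)
    res <- NULL
    if (nrow(idx)) {
      hts <- (zz[idx[, 1]] + zz[idx[, 1] + 1L]) / 2
      dir <- ifelse(water[cbind(idx[, 1] + 1L, idx[, 2])],
                    "air_to_water", "water_to_air")
      res <- data.frame(offset_um = offsets_um[k],
                        azimuth = az[idx[, 2]],
                        height = hts, direction = dir)
    }
    # liquid already present at the scan top: record the top as wetted
    top_wet <- which(water[1, ])
    if (length(top_wet)) {
      res <- rbind(data.frame(offset_um = offsets_um[k],
                              azimuth = az[top_wet], height = zz[1],
                              direction = "air_to_water"), res)
    }
    if (!is.null(res)) {
      res <- res[order(res$azimuth, -res$height), ]
      res$crossing <- stats::ave(res$height, res$azimuth,
                                 FUN = seq_along)
      first <- res[res$crossing == 1L & res$direction == "air_to_water", ]
      contact[match(first$azimuth, az), k] <- first$height
    }
    crossings[[k]] <- res
  }
  crossings <- do.call(rbind, crossings)
  rownames(crossings) <- NULL
  structure(list(crossings = crossings,
                 contact = contact,
                 azimuths = az,
                 offsets_um = offsets_um,
                 z_step = z_step, azimuth_step = azimuth_step,
                 n_samples_per_offset = nz * na,
                 n_outside_support = n_outside),
            class = "contact_line_set")
}

#' @export
print.contact_line_set <- function(x, ...) {
  cat(sprintf(paste0("Contact line set: %d offsets (%s um), %d azimuths, ",
                     "%d samples per offset\n"),
              length(x$offsets_um),
              paste(x$offsets_um, collapse = ", "),
              length(x$azimuths), x$n_samples_per_offset))
  wet <- colSums(!is.na(x$contact))
  cat("  wetted azimuths per offset:",
      paste(sprintf("%s:%d", colnames(x$contact), wet), collapse = ", "),
      "\n")
  if (x$n_outside_support > 0)
    cat("  note:", x$n_outside_support,
        "samples outside the field support were read as air\n")
  invisible(x)
}

#' Plot extracted contact lines
#'
#' @param x a [extract_contact_lines()] result
#' @param ... passed to [graphics::matplot()]
#' @export
plot.contact_line_set <- function(x, ...) {
  graphics::matplot(x$azimuths, x$contact, type = "l", lty = 1,
                    xlab = "azimuth (deg)", ylab = "contact height (mm)",
                    ...)
  graphics::abline(v = 180, lty = 2)
  graphics::legend("topleft", legend = colnames(x$contact),
                   col = seq_len(ncol(x$contact)), lty = 1, cex = 0.7)
  invisible(x)
}

# Azimuth mask for a possibly wrap-around window c(from, to) in degrees.
azimuth_in_window <- function(az, window) {
  a <- az %% 360; f <- window[1] %% 360; t <- window[2] %% 360
  if (f <= t) a >= f & a <= t else a >= f | a <= t
}

#' Bracket the wall-film thickness from a multi-offset extraction
#'
#' At moderate viscosity a thin liquid film clings to the entire inner wall
#' up to roughly the maximal liquid height, so probes at small wall-normal
#' offsets report a nearly constant contact height (the film top) at every
#' azimuth, while probes beyond the film report the bulk contact line. Over
#' azimuths in a window far from the bulk's leading edge, this function
#' returns the largest offset still reading the film (lower bound) and the
#' smallest offset that falls through to the bulk (upper bound). The
#' bracket granularity is the offset ladder step (200 um by default).
#'
#' A film is recognised by its azimuthal flatness: within the window the
#' film top varies by at most `flat_tol`, while a bulk contact line follows
#' the curved free surface. A nearly flat free surface (vanishing shaking
#' frequency) is therefore indistinguishable from a thick film at every
#' offset; see the package vignette.
#'
#' @param cls a [extract_contact_lines()] result with at least two offsets
#' @param window azimuth window `c(from, to)` in degrees (may wrap through
#'   0); default is the quadrant opposite the leading edge
#' @param height_tol offsets whose median contact height lies within this
#'   tolerance (mm) of the film top still count as film
#' @param flat_tol maximal azimuthal range (mm) of a film-like line within
#'   the window
#' @return object of class `film_estimate` with `lower_um`, `upper_um`
#'   (`Inf` when the film exceeds the deepest offset), `film_top_mm`, and
#'   the per-offset window medians
#' @export
estimate_film_thickness <- function(cls, window = c(300, 60),
                                    height_tol = 1.5, flat_tol = 3) {
  stopifnot(inherits(cls, "contact_line_set"))
  if (length(cls$offsets_um) < 2L)
    stop("at least two offsets are required to bracket a film")
  sel <- azimuth_in_window(cls$azimuths, window)
  if (!any(sel)) stop("empty azimuth window")
  h <- cls$contact[sel, , drop = FALSE]
  med <- apply(h, 2, function(v) {
    if (mean(is.na(v)) > 0.5) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  rng <- apply(h, 2, function(v) {
    if (mean(is.na(v)) > 0.5) Inf else diff(range(v, na.rm = TRUE))
  })
  film_like <- !is.na(med) & rng <= flat_tol &
    abs(med - med[1]) <= height_tol
  est <- if (!film_like[1]) {
    # smallest offset already reads the bulk: no resolvable film
    list(lower_um = 0, upper_um = cls$offsets_um[1])
  } else {
    k <- which(!film_like)
    if (!length(k)) {
      list(lower_um = cls$offsets_um[length(cls$offsets_um)],
           upper_um = Inf)
    } else {
      k <- min(k)
      list(lower_um = cls$offsets_um[k - 1L], upper_um = cls$offsets_um[k])
    }
  }
  structure(c(est, list(film_top_mm = unname(med[1]),
                        window = window,
                        offset_medians_mm = med)),
            class = "film_estimate")
}

#' @export
print.film_estimate <- function(x, ...) {
  if (x$lower_um <= 0) {
    cat(sprintf("No wall film resolved (thinner than %g um if present)\n",
                x$upper_um))
  } else if (is.infinite(x$upper_um)) {
    cat(sprintf("Wall film thicker than the deepest offset (%g um)\n",
                x$lower_um))
  } else {
    cat(sprintf("Wall film thickness between %g and %g um (film top %.1f mm)\n",
                x$lower_um, x$upper_um, x$film_top_mm))
  }
  invisible(x)
}

#' Azimuthal shift of the contact-line apex
#'
#' Signed azimuthal distance from the reference (centrifugal) direction to
#' the azimuth of the maximal contact height at one offset; positive values
#' mean the apex trails the centrifugal direction, i.e. the bulk liquid is
#' shifted against the shaking direction, as viscous forces do. Tying
#' azimuths (the apex flattened by the vertical sampling grid) are resolved
#' by their circular mean.
#'
#' @param cls a [extract_contact_lines()] result
#' @param reference_azimuth degrees; 180 is the centrifugal direction
#' @param offset_um which offset to read; defaults to the smallest
#' @return shift in degrees, in `[-180, 180)`
#' @export
apex_shift <- function(cls, reference_azimuth = 180, offset_um = NULL) {
  stopifnot(inherits(cls, "contact_line_set"))
  if (is.null(offset_um)) offset_um <- cls$offsets_um[1]
  k <- match(offset_um, cls$offsets_um)
  if (is.na(k)) stop("offset ", offset_um, " um was not sampled")
  h <- cls$contact[, k]
  ok <- !is.na(h)
  if (!any(ok)) stop("no contact line at offset ", offset_um, " um")
  if (diff(range(h[ok])) < cls$z_step / 2)
    stop("degenerate flat contact line: apex azimuth is undefined")
  apex <- apex_from_line(cls$azimuths[ok], h[ok], tie_tol = 1e-9)
  ((apex$azimuth - reference_azimuth + 180) %% 360) - 180
}

#' Write per-offset contact lines as delimited text
#'
#' One tab-separated file per offset with columns azimuth_deg,
#' crossing_index, height_mm, direction.
#'
#' @param cls a [extract_contact_lines()] result
#' @param dir output directory
#' @param prefix file-name prefix
#' @return the written paths, invisibly
#' @export
write_contact_line_set <- function(cls, dir, prefix = "contact_line") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (o in cls$offsets_um) {
    cc <- cls$crossings[cls$crossings$offset_um == o, ]
    out <- data.frame(azimuth_deg = cc$azimuth,
                      crossing_index = cc$crossing,
                      height_mm = cc$height,
                      direction = cc$direction)
    p <- file.path(dir, sprintf("%s_%gum.tsv", prefix, o))
    utils::write.table(out, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
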