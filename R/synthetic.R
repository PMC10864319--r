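#' Specification of a synthetic VOF-style field
#'
#' Describes a synthetic volume-fraction (and flow) field emulating the
#' output of a volume-of-fluid solver: a rotating bulk shaped by the
#' inviscid paraboloid model, optionally rotated by a phase shift about the
#' flask axis (mimicking the viscous lag of the bulk behind the centrifugal
#' direction), plus a thin wall film of configurable thickness up to a
#' configurable height, with the interface smeared over roughly one cell.
#' Fields generated from the same spec are bit-identical.
#'
#' @param geometry a [flask_geometry()]
#' @param cond an [operating_condition()]
#' @param fluid a [fluid_properties()]
#' @param phase_shift bulk rotation against the shaking direction (deg);
#'   0 reproduces the inviscid model
#' @param film_thickness_um wall-film thickness (um); 0 disables the film.
#'   Real films span roughly 50 to 800 um depending on viscosity.
#' @param film_top_height_mm film extends up to this height; defaults to
#'   the bulk's maximal contact height
#' @param film_taper fractional thinning of the film towards its top (the
#'   film drains under gravity and is slightly thinner near the maximal
#'   liquid height); applied linearly over the top `film_taper` fraction of
#'   the film height
#' @param interface_smear interface smearing width in cells (0 to 2)
#' @param cell_size_mm nominal cell edge length (mm); must resolve the
#'   flask diameter with at least 20 cells
#' @param seed integer seed recorded with the field (the construction is
#'   deterministic; the seed feeds any downstream stochastic use)
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(geometry, cond, fluid, phase_shift = 0,
                           film_thickness_um = 0, film_top_height_mm = NULL,
                           film_taper = 0.1, interface_smear = 1,
                           cell_size_mm = 1.5, seed = 1L) {
  stopifnot(inherits(geometry, "flask_geometry"),
            inherits(cond, "operating_condition"),
            inherits(fluid, "fluid_properties"))
  if (film_thickness_um < 0) stop("film thickness must be >= 0")
  if (interface_smear < 0 || interface_smear > 2)
    stop("interface smear must lie in [0, 2] cells")
  if (cell_size_mm > geometry$dims$max_diameter / 20)
    stop("cell size must resolve the flask diameter with >= 20 cells")
  structure(list(geometry = geometry, cond = cond, fluid = fluid,
                 phase_shift = phase_shift,
                 film_thickness_um = film_thickness_um,
                 film_top_height_mm = film_top_height_mm,
                 film_taper = film_taper,
                 interface_smear = interface_smear,
                 cell_size_mm = cell_size_mm,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Normal inset distance (mm) from the inner wall, positive inside the
# liquid-side of the wall. Torus segment below the junction height, cone
# above; for the smooth variant the two agree at the junction by tangency.
wall_inset_distance <- function(geom, rho, z) {
  rt <- geom$dims$torus_radius
  d <- numeric(length(rho))
  on_t <- z <= geom$junction_z + 1e-9
  d[on_t] <- rt - sqrt((rho[on_t] - geom$centre_radius)^2 + (z[on_t] - rt)^2)
  a <- geom$cone_half_angle * pi / 180
  d[!on_t] <- -(rho[!on_t] - geom$junction_r) * cos(a) -
    (z[!on_t] - geom$junction_z) * sin(a)
  d
}

#' Generate a synthetic volume-fraction field
#'
#' Realises the spec as an [alpha_field()]: alpha is 1 inside the
#' mechanistic bulk rotated by the phase shift, plus the wall film, and
#' transitions linearly to 0 across the interface over the smear width.
#' The analytic ground truth (bulk contact line, film top, solved
#' paraboloid) is attached as attribute `ground_truth` and doubles as the
#' oracle for extraction tests.
#'
#' @param spec a [synthetic_spec()]
#' @return an [alpha_field()] with attribute `ground_truth`
#' @export
generate_alpha_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  geom <- spec$geometry
  dist <- solve_fill(geom, spec$cond)
  par <- dist$paraboloid
  delta <- spec$phase_shift * pi / 180
  w <- max(spec$interface_smear * spec$cell_size_mm, 1e-9)
  film_T <- spec$film_thickness_um / 1000  # mm
  film_top <- if (is.null(spec$film_top_height_mm)) dist$max_height
              else spec$film_top_height_mm
  taper <- spec$film_taper
  sub_res <- film_T > 0 && film_T < spec$cell_size_mm / 2
  if (sub_res)
    warning("film thinner than half a cell: generated but sub-resolution",
            call. = FALSE)

  fun <- function(x, y, z) {
    rho <- sqrt(x^2 + y^2)
    th <- atan2(y, x)
    h <- paraboloid_height(par, rho, th - delta)
    a_bulk <- pmin(pmax(0.5 + (h - z) / w, 0), 1)
    if (film_T > 0) {
      din <- wall_inset_distance(geom, rho, z)
      zone <- taper * film_top
      u <- pmin(pmax((z - (film_top - zone)) / max(zone, 1e-9), 0), 1)
      thick <- film_T * (1 - taper * u)
      sd_film <- pmin(thick - din, film_top - z)  # signed dist into film
      a_film <- pmin(pmax(0.5 + sd_film / w, 0), 1)
      a_film[din < 0] <- 0
      a_bulk <- pmax(a_bulk, a_film)
    }
    a_bulk
  }

  gt_line <- dist$contact_line[dist$contact_line$crossing == 1L, ]
  gt_line$azimuth <- (gt_line$azimuth + spec$phase_shift) %% 360
  gt_line <- gt_line[order(gt_line$azimuth), ]
  gt <- list(paraboloid = par,
             phase_shift = spec$phase_shift,
             bulk_contact_line = gt_line[, c("azimuth", "height")],
             bulk_max_height = dist$max_height,
             bulk_max_azimuth = (dist$max_height_azimuth +
                                   spec$phase_shift) %% 360,
             film_thickness_um = spec$film_thickness_um,
             film_top_mm = if (film_T > 0) film_top else NA_real_,
             sub_resolution = sub_res,
             V_L_mL = spec$cond$V_L * 1e6,
             seed = spec$seed)
  out <- alpha_field(fun, geom, meta = list(synthetic = TRUE,
                                            seed = spec$seed))
  attr(out, "ground_truth") <- gt
  out
}

# Structured cylindrical-shell mesh clipped to the flask wall. Cell volumes
# are the analytic shell volumes scaled by the wall-inside fraction of the
# (r, z) cross-section, estimated on a sub-grid; this keeps volume
# integrals honest near the curved wall.
synthetic_mesh <- function(spec, z_max = NULL, n_sub = 3L) {
  geom <- spec$geometry
  h <- spec$cell_size_mm
  r_max <- geom$centre_radius + geom$dims$torus_radius
  if (is.null(z_max)) z_max <- geom$dims$top_height
  z_max <- min(z_max, geom$dims$top_height)
  r_edges <- seq(0, r_max, by = h)
  if (r_edges[length(r_edges)] < r_max) r_edges <- c(r_edges, r_max)
  z_edges <- seq(0, z_max, by = h)
  if (z_edges[length(z_edges)] < z_max) z_edges <- c(z_edges, z_max)
  n_th <- max(8L, ceiling(2 * pi * r_max / h))
  th_c <- (seq_len(n_th) - 0.5) * (2 * pi / n_th)
  dth <- 2 * pi / n_th

  nr <- length(r_edges) - 1L
  nz <- length(z_edges) - 1L
  # wall-inside fraction of each (r, z) cell from an n_sub x n_sub sub-grid
  frac <- matrix(0, nr, nz)
  off <- (seq_len(n_sub) - 0.5) / n_sub
  for (i in seq_len(nr)) {
    rs <- r_edges[i] + off * (r_edges[i + 1L] - r_edges[i])
    for (j in seq_len(nz)) {
      zs <- z_edges[j] + off * (z_edges[j + 1L] - z_edges[j])
      rw <- wall_radius_at_height(geom, zs)
      frac[i, j] <- mean(outer(rs, rw, "<="))
    }
  }
  keep <- which(frac > 0, arr.ind = TRUE)
  shell_vol <- 0.5 * (r_edges[keep[, 1] + 1L]^2 - r_edges[keep[, 1]]^2) *
    dth * (z_edges[keep[, 2] + 1L] - z_edges[keep[, 2]])
  r_c <- (r_edges[keep[, 1]] + r_edges[keep[, 1] + 1L]) / 2
  z_c <- (z_edges[keep[, 2]] + z_edges[keep[, 2] + 1L]) / 2

  n_rz <- nrow(keep)
  list(r_c = rep(r_c, times = n_th),
       th_c = rep(th_c, each = n_rz),
       z_c = rep(z_c, times = n_th),
       volume_mm3 = rep(shell_vol * frac[keep], times = n_th),
       rz_index = rep(seq_len(n_rz), times = n_th),
       r_edges = r_edges, z_edges = z_edges, keep = keep,
       frac = frac[keep], n_sub = n_sub, n_th = n_th)
}

# Cell-averaged alpha over the wall-inside part of each cell: the (r, z)
# sub-grid restricted to inside points, at the cell's azimuthal centre.
mesh_cell_alpha <- function(mesh, geom, fun) {
  n_sub <- mesh$n_sub
  off <- (seq_len(n_sub) - 0.5) / n_sub
  keep <- mesh$keep
  n_rz <- nrow(keep)
  # sub-point coordinates per kept (r, z) cell
  rs <- mesh$r_edges[keep[, 1]] +
    rep(off, each = n_rz) * (mesh$r_edges[keep[, 1] + 1L] -
                               mesh$r_edges[keep[, 1]])
  zs <- mesh$z_edges[keep[, 2]] +
    rep(off, each = n_rz) * (mesh$z_edges[keep[, 2] + 1L] -
                               mesh$z_edges[keep[, 2]])
  rs <- matrix(rs, n_rz, n_sub)
  zs <- matrix(zs, n_rz, n_sub)
  alpha <- numeric(length(mesh$r_c))
  for (it in seq_len(mesh$n_th)) {
    th <- ((it - 0.5) * 2 * pi / mesh$n_th)
    asum <- matrix(0, n_rz, 1)
    wsum <- matrix(0, n_rz, 1)
    for (ir in seq_len(n_sub)) {
      for (iz in seq_len(n_sub)) {
        r <- rs[, ir]; z <- zs[, iz]
        inside <- r <= wall_radius_at_height(geom, z)
        a <- fun(r * cos(th), r * sin(th), z)
        asum <- asum + a * inside
        wsum <- wsum + inside
      }
    }
    idx <- (it - 1L) * n_rz + seq_len(n_rz)
    alpha[idx] <- ifelse(wsum > 0, asum / pmax(wsum, 1), 0)
  }
  alpha
}

#' Generate a synthetic flow field with closed-form dissipation
#'
#' Realises the spec on the structured cylindrical mesh and attaches
#' analytic strain, turbulence and volume-fraction data so that the
#' dissipation integral can be checked against a closed form:
#' \describe{
#'   \item{quiescent}{no motion; every dissipation channel is zero.}
#'   \item{solid_body}{rigid rotation: the strain measure vanishes exactly,
#'     and the turbulent channel carries `k0`, `omega0` so
#'     `eps = beta_star * k0 * omega0` in the bulk.}
#'   \item{shear_layer}{uniform simple shear `gamma_dot`, so the mean-flow
#'     channel carries `eps = (eta/rho) * gamma_dot^2` in the bulk.}
#' }
#' Cells above the bulk free surface (the wall film and the gas) carry
#' near-zero gradients and turbulence: movement in the film is driven by
#' gravity-led drainage, with velocity gradients far below those of the
#' bulk, which is why the film contributes negligible power.
#'
#' @param spec a [synthetic_spec()]
#' @param profile one of `"quiescent"`, `"solid_body"`, `"shear_layer"`
#' @param k0 turbulent kinetic energy of the bulk (m^2/s^2)
#' @param omega0 specific dissipation rate of the bulk (1/s)
#' @param gamma_dot shear rate of the shear layer (1/s)
#' @param z_max mesh height cap (mm); defaults to just above the liquid
#' @return a [field_set()] with attributes `ground_truth` (closed-form bulk
#'   dissipation rates) and `mesh` (cell centres, for [write_field_vtk()])
#' @export
generate_flow_field <- function(spec,
                                profile = c("quiescent", "solid_body",
                                            "shear_layer"),
                                k0 = 1e-3, omega0 = 10, gamma_dot = 100,
                                z_max = NULL) {
  profile <- match.arg(profile)
  stopifnot(inherits(spec, "synthetic_spec"))
  geom <- spec$geometry
  af <- generate_alpha_field(spec)
  gt <- attr(af, "ground_truth")
  if (is.null(z_max))
    z_max <- min(geom$dims$top_height,
                 max(gt$bulk_max_height,
                     if (is.na(gt$film_top_mm)) 0 else gt$film_top_mm) + 5)
  mesh <- synthetic_mesh(spec, z_max = z_max)
  alpha <- mesh_cell_alpha(mesh, geom, af$fun)

  n <- length(alpha)
  # Bulk cells lie at or below the (rotated) bulk free surface, with the
  # smeared interface ribbon counted as bulk; everything above is wall film
  # or gas and carries near-zero gradients and turbulence, reflecting the
  # gravity-led drainage flow of the film.
  w <- max(spec$interface_smear * spec$cell_size_mm, 1e-9)
  th <- mesh$th_c - spec$phase_shift * pi / 180
  h_bulk <- paraboloid_height(gt$paraboloid, mesh$r_c, th)
  above_bulk <- mesh$z_c > h_bulk + max(w, spec$cell_size_mm)
  S2 <- rep(0, n); k <- rep(0, n); om <- rep(0, n)
  eps_m_bulk <- 0; eps_t_bulk <- 0
  nu <- spec$fluid$viscosity / spec$fluid$density
  if (profile == "solid_body") {
    k[!above_bulk] <- k0
    om[!above_bulk] <- omega0
    eps_t_bulk <- 0.09 * k0 * omega0
  } else if (profile == "shear_layer") {
    S2[!above_bulk] <- gamma_dot^2
    eps_m_bulk <- nu * gamma_dot^2
  }
  S2[above_bulk] <- 1e-12

  fs <- field_set(volume = mesh$volume_mm3 * 1e-9, alpha = alpha,
                  fluid = spec$fluid, S2 = S2, k = k, omega = om)
  attr(fs, "ground_truth") <- c(gt, list(
    profile = profile,
    epsilon_mean_bulk = eps_m_bulk,
    epsilon_turb_bulk = eps_t_bulk,
    epsilon_total_bulk = eps_m_bulk + eps_t_bulk))
  attr(fs, "mesh") <- data.frame(x = mesh$r_c * cos(mesh$th_c),
                                 y = mesh$r_c * sin(mesh$th_c),
                                 z = mesh$z_c,
                                 above_bulk = above_bulk)
  fs
}

#' Write a synthetic field set to VTK with a ground-truth sidecar
#'
#' Writes the cell centres with `alpha`, `k`, `omega`, `S2` and `V` arrays
#' as legacy ASCII VTK, plus a JSON sidecar holding the analytic ground
#' truth, so that the file round-trips through [read_field_vtk()] and
#' [read_alpha_vtk()].
#'
#' @param fs a [generate_flow_field()] result
#' @param file VTK output path; the sidecar is written to
#'   `paste0(file, ".json")`
#' @return the VTK path, invisibly
#' @export
write_field_vtk <- function(fs, file) {
  mesh <- attr(fs, "mesh")
  if (is.null(mesh)) stop("field set carries no mesh (not synthetic?)")
  write_vtk_points(as.matrix(mesh[, c("x", "y", "z")]),
                   list(alpha = fs$alpha, k = fs$k, omega = fs$omega,
                        S2 = fs$S2, V = fs$volume),
                   file, title = "synthetic shake flask field")
  gt <- attr(fs, "ground_truth")
  gt$bulk_contact_line <- NULL  # tabular; kept in the R object only
  gt$paraboloid <- unclass(gt$paraboloid)
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paste0(file, ".json"))
  invisible(file)
}
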