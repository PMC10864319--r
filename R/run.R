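# Configuration-driven pipeline runners. A run configuration is a nested
# list (usually parsed from YAML) with blocks mirroring the analysis
# stages; unknown keys are rejected so typos fail loudly. Every runner
# writes a provenance record (config hash, seed, package version) next to
# its outputs, and identical configurations reproduce identical files.

run_config_schema <- list(
  geometry = c("torus_radius", "max_diameter", "height_of_max_diameter",
               "top_diameter", "top_height", "bottom_diameter",
               "transition"),
  condition = c("n_rpm", "n_hz", "d0_cm", "V_L_mL", "temperature",
                "run_time", "ramp_time"),
  fluid = c("density", "viscosity", "surface_tension", "contact_angle"),
  extraction = c("z_step", "azimuth_step", "offsets_um", "z_max",
                 "film_window", "apex_offset_um"),
  synthetic = c("phase_shift", "film_thickness_um", "film_top_height_mm",
                "film_taper", "interface_smear", "cell_size_mm"),
  power = c("n_rpm", "V_L_mL", "eta_mPas", "rho", "d"),
  output = c("dir"),
  seed = NULL, log_level = NULL)

#' Read and validate a run configuration
#'
#' @param x path to a YAML file, or an already-parsed nested list
#' @return validated configuration list of class `run_config`
#' @export
read_run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  bad <- setdiff(names(cfg), names(run_config_schema))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(names(run_config_schema), collapse = ", "), ")")
  for (blk in names(cfg)) {
    allowed <- run_config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      stop("unknown key(s) in block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  dims_args <- g[setdiff(names(g), "transition")]
  dims <- do.call(flask_dimensions, dims_args %||% list())
  flask_geometry(dims, transition = g$transition %||% "smooth")
}

config_condition <- function(cfg) {
  if (is.null(cfg$condition))
    stop("configuration needs a 'condition' block")
  do.call(operating_condition, cfg$condition)
}

config_fluid <- function(cfg) {
  do.call(fluid_properties,
          cfg$fluid %||% list(viscosity = 0.89e-3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a hash of the serialised configuration, for provenance records.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_provenance <- function(cfg, dir, what) {
  rec <- list(tool = "shakeflask",
              version = as.character(utils::packageVersion("shakeflask")),
              stage = what,
              config_hash = config_hash(cfg),
              seed = cfg$seed %||% NA)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "provenance.json"))
}

prepare_outdir <- function(cfg) {
  dir <- cfg$output$dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Run the mechanistic liquid-distribution model from a configuration
#'
#' Solves the inviscid paraboloid model for the configured geometry and
#' operating condition and writes the contact line (`contact_line.tsv`),
#' a summary (`mechanistic_summary.json`) and a provenance record to the
#' configured output directory.
#'
#' @param config a [read_run_config()] result, a list, or a YAML path
#' @return the summary list, invisibly
#' @export
run_mechanistic <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  geom <- config_geometry(cfg)
  cond <- config_condition(cfg)
  step <- cfg$extraction$azimuth_step %||% 1
  fit <- solve_fill(geom, cond, azimuth_step = step)
  dir <- prepare_outdir(cfg)
  write_contact_line(fit$contact_line, file.path(dir, "contact_line.tsv"))
  summary <- list(max_height_mm = fit$max_height,
                  max_height_azimuth_deg = fit$max_height_azimuth,
                  achieved_volume_mL = fit$achieved_volume_mL,
                  z0_mm = fit$paraboloid$z0,
                  curvature_per_mm = fit$paraboloid$curvature,
                  transition = geom$transition)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "mechanistic_summary.json"))
  write_provenance(cfg, dir, "mechanistic")
  invisible(summary)
}

#' Run contact-line extraction from a configuration
#'
#' Extracts multi-offset contact lines either from a VTK volume-fraction
#' file or, when none is given, from the synthetic field described by the
#' configuration's `synthetic` block. Writes per-offset contact-line
#' tables, a JSON summary (maximal height, apex shift, film bracket) and a
#' provenance record.
#'
#' @param config configuration (see [read_run_config()])
#' @param field_file optional VTK file carrying the volume fraction
#' @return the summary list, invisibly
#' @export
run_extract <- function(config, field_file = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  geom <- config_geometry(cfg)
  field <- if (!is.null(field_file)) {
    read_alpha_vtk(field_file, geom)
  } else {
    cond <- config_condition(cfg)
    fluid <- config_fluid(cfg)
    sargs <- c(list(geometry = geom, cond = cond, fluid = fluid,
                    seed = cfg$seed %||% 1L), cfg$synthetic)
    generate_alpha_field(do.call(synthetic_spec, sargs))
  }
  ex <- cfg$extraction
  cls <- extract_contact_lines(field,
                               z_step = ex$z_step %||% 0.5,
                               azimuth_step = ex$azimuth_step %||% 1,
                               offsets_um = ex$offsets_um %||%
                                 c(50, 250, 450, 650, 850, 1050),
                               z_max = ex$z_max)
  dir <- prepare_outdir(cfg)
  write_contact_line_set(cls, dir)
  film <- tryCatch(estimate_film_thickness(
    cls, window = ex$film_window %||% c(300, 60)),
    error = function(e) NULL)
  shift <- tryCatch(apex_shift(cls, offset_um = ex$apex_offset_um),
                    error = function(e) NA_real_)
  summary <- list(max_height_mm = suppressWarnings(max(cls$contact,
                                                       na.rm = TRUE)),
                  apex_shift_deg = shift,
                  film_lower_um = if (is.null(film)) NA else film$lower_um,
                  film_upper_um = if (is.null(film)) NA else film$upper_um,
                  n_samples_per_offset = cls$n_samples_per_offset)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "extraction_summary.json"))
  write_provenance(cfg, dir, "extract")
  invisible(summary)
}

#' Run a power-input computation from a configuration
#'
#' With a VTK field file, integrates the energy dissipation over the
#' liquid phase; without one, evaluates the Ne'-Re correlation over the
#' grid in the configuration's `power` block. Both paths label their
#' outputs with the method used.
#'
#' @param config configuration (see [read_run_config()])
#' @param field_file optional VTK field file (arrays alpha, V, S2, k,
#'   omega)
#' @return the power result or the correlation table, invisibly
#' @export
run_power <- function(config, field_file = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir <- prepare_outdir(cfg)
  if (!is.null(field_file)) {
    fluid <- config_fluid(cfg)
    fs <- read_field_vtk(field_file, fluid)
    res <- epsilon_total(fs)
    power_result_json(res, file.path(dir, "power_dissipation.json"))
    write_provenance(cfg, dir, "power")
    return(invisible(res))
  }
  p <- cfg$power
  if (is.null(p))
    stop("run_power needs either a field file or a 'power' block ",
         "with the correlation grid")
  tab <- power_table(n_rpm = p$n_rpm %||% seq(180, 380, 10),
                     V_L_mL = p$V_L_mL %||% c(25, 40),
                     eta_mPas = p$eta_mPas %||% c(1, 16),
                     rho = p$rho %||% 1000,
                     d = p$d %||% 0.0816)
  utils::write.table(tab, file.path(dir, "power_correlation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_provenance(cfg, dir, "power")
  invisible(tab)
}
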