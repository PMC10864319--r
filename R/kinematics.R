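#' Operating condition of an orbitally shaken flask
#'
#' Shaking frequency, orbital (shaking) diameter and filling volume, with
#' the start-up ramp settings of the rotating-force model. Inputs use the
#' field's customary units (rpm, cm, mL) and are stored in SI.
#'
#' @param n_rpm shaking frequency in rpm (alternative to `n_hz`)
#' @param d0_cm shaking diameter in cm
#' @param V_L_mL filling volume in mL
#' @param n_hz shaking frequency in 1/s; give exactly one of `n_rpm`, `n_hz`
#' @param temperature metadata, degrees C
#' @param run_time total simulated time (s)
#' @param ramp_time the frequency ramps linearly from standstill to `n`
#'   over this initial interval (s)
#' @return object of class `operating_condition` with fields `n` (1/s),
#'   `d0` (m), `V_L` (m^3) and the ramp settings
#' @export
#' @examples
#' operating_condition(n_rpm = 250, d0_cm = 2.5, V_L_mL = 40)
operating_condition <- function(n_rpm = NULL, d0_cm, V_L_mL, n_hz = NULL,
                                temperature = 25, run_time = 10,
                                ramp_time = 0.5) {
  if (is.null(n_rpm) == is.null(n_hz))
    stop("give exactly one of n_rpm and n_hz")
  n <- if (is.null(n_hz)) n_rpm / 60 else n_hz
  if (!is.numeric(n) || n < 0) stop("shaking frequency must be >= 0")
  if (d0_cm <= 0) stop("shaking diameter must be > 0")
  if (V_L_mL <= 0) stop("filling volume must be > 0")
  if (ramp_time > run_time) stop("ramp_time must not exceed run_time")
  structure(list(n = n, d0 = d0_cm / 100, V_L = V_L_mL * 1e-6,
                 temperature = temperature,
                 run_time = run_time, ramp_time = ramp_time),
            class = "operating_condition")
}

#' @export
print.operating_condition <- function(x, ...) {
  cat(sprintf(paste0("Operating condition: n = %.4g rpm, d0 = %.3g cm, ",
                     "V_L = %.4g mL (T = %.3g degC)\n"),
              x$n * 60, x$d0 * 100, x$V_L * 1e6, x$temperature))
  invisible(x)
}

#' Fluid properties
#'
#' @param density kg/m^3
#' @param viscosity dynamic viscosity, Pa s
#' @param surface_tension N/m
#' @param contact_angle degrees, in (0, 180)
#' @return object of class `fluid_properties`
#' @export
#' @examples
#' water <- fluid_properties(viscosity = 0.89e-3)
fluid_properties <- function(density = 1000, viscosity,
                             surface_tension = 0.07, contact_angle = 20) {
  if (density <= 0 || viscosity <= 0 || surface_tension <= 0)
    stop("density, viscosity and surface tension must be > 0")
  if (contact_angle <= 0 || contact_angle >= 180)
    stop("contact angle must lie in (0, 180) degrees")
  structure(list(density = density, viscosity = viscosity,
                 surface_tension = surface_tension,
                 contact_angle = contact_angle),
            class = "fluid_properties")
}

#' Angular velocity of the shaking motion
#'
#' @param cond an [operating_condition()]
#' @return `2 * pi * n` in rad/s
#' @export
angular_velocity <- function(cond) {
  stopifnot(inherits(cond, "operating_condition"))
  2 * pi * cond$n
}

# Effective (ramped) frequency and coherently integrated phase at time t.
# During the ramp n_eff(t) = n * t / ramp_time, and the phase is the time
# integral of the ramped angular velocity, so phase(t) = pi * n * t^2 / t_r
# for t < t_r.
ramped_state <- function(cond, t) {
  tr <- cond$ramp_time
  n <- cond$n
  in_ramp <- tr > 0 & t < tr
  n_eff <- ifelse(in_ramp, n * t / tr, n)
  phase <- ifelse(in_ramp,
                  pi * n * t^2 / tr,
                  pi * n * tr + 2 * pi * n * (t - tr))
  list(n_eff = n_eff, phase = phase)
}

#' Rotating centrifugal body force
#'
#' The cyclic force (per unit mass) that models orbital shaking of a
#' stationary flask: `F_x = w^2 (d0/2) cos(w t)`, `F_y = w^2 (d0/2) sin(w t)`
#' with `w = 2 pi n`. During the initial ramp the frequency grows linearly
#' from standstill, and the phase is the coherent integral of the ramped
#' angular velocity; from `ramp_time` on the magnitude is the constant
#' `w^2 d0 / 2` while the direction rotates at `w`.
#'
#' @param cond an [operating_condition()]
#' @param t times (s), vectorised
#' @return data.frame with columns `t`, `F_x`, `F_y`, `magnitude` (m/s^2)
#' @export
centrifugal_force <- function(cond, t) {
  stopifnot(inherits(cond, "operating_condition"), all(t >= 0))
  st <- ramped_state(cond, t)
  w_eff <- 2 * pi * st$n_eff
  mag <- w_eff^2 * cond$d0 / 2
  data.frame(t = t,
             F_x = mag * cos(st$phase),
             F_y = mag * sin(st$phase),
             magnitude = mag)
}

#' Write the body-force schedule as delimited text
#'
#' Tab-separated columns t, F_x, F_y for coupling to an external solver.
#'
#' @param cond an [operating_condition()]
#' @param file output path
#' @param dt time step of the table (s)
#' @return the file path, invisibly
#' @export
write_force_schedule <- function(cond, file, dt = 0.01) {
  tt <- seq(0, cond$run_time, by = dt)
  f <- centrifugal_force(cond, tt)
  utils::write.table(f[, c("t", "F_x", "F_y")], file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
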