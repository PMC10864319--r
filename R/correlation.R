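#' Flask Reynolds number
#'
#' `Re = rho * n * d^2 / eta` with `d` the maximum inner flask diameter.
#'
#' @param rho liquid density (kg/m^3)
#' @param n shaking frequency (1/s)
#' @param d maximum inner flask diameter (m)
#' @param eta dynamic viscosity (Pa s)
#' @return Reynolds number (dimensionless)
#' @export
#' @examples
#' reynolds(1000, 250 / 60, 0.0816, 0.89e-3)  # about 31,000
reynolds <- function(rho, n, d, eta) {
  if (any(c(rho, n, d, eta) <= 0)) stop("all inputs must be > 0")
  rho * n * d^2 / eta
}

#' Modified Newton number from the power correlation
#'
#' `Ne' = 70 Re^-1 + 25 Re^-0.6 + 1.5 Re^-0.2`, the out-of-phase-free power
#' correlation for unbaffled shake flasks; strictly decreasing in Re. The
#' shaking-diameter dependence is deliberately not part of this form.
#'
#' @param Re Reynolds numbers, > 0; vectorised
#' @return modified Newton numbers (dimensionless)
#' @export
ne_prime <- function(Re) {
  if (any(Re <= 0)) stop("Re must be > 0")
  70 / Re + 25 * Re^-0.6 + 1.5 * Re^-0.2
}

#' Power input from the Ne'-Re correlation
#'
#' Evaluates the correlation for one operating point:
#' `P = Ne'(Re) * rho * n^3 * d^4 * V_L^(1/3)` and `P/V = P / V_L`.
#'
#' @param cond an [operating_condition()]
#' @param fluid a [fluid_properties()]
#' @param d maximum inner flask diameter (m); 0.0816 m for the default
#'   250 mL flask
#' @return object of classes `dimensionless_point` and `power_result` with
#'   `Re`, `Ne_prime`, `P` (W), `P_over_V` (W/m^3) and the echoed inputs
#' @export
#' @examples
#' pt <- power_from_correlation(
#'   operating_condition(n_rpm = 250, d0_cm = 2.5, V_L_mL = 40),
#'   fluid_properties(viscosity = 0.89e-3))
#' pt$Re
power_from_correlation <- function(cond, fluid, d = 0.0816) {
  stopifnot(inherits(cond, "operating_condition"),
            inherits(fluid, "fluid_properties"))
  Re <- reynolds(fluid$density, cond$n, d, fluid$viscosity)
  Ne <- ne_prime(Re)
  P <- Ne * fluid$density * cond$n^3 * d^4 * cond$V_L^(1 / 3)
  structure(list(Re = Re, Ne_prime = Ne, P = P,
                 P_over_V = P / cond$V_L,
                 method = "correlation",
                 inputs = list(rho = fluid$density, eta = fluid$viscosity,
                               n = cond$n, d = d, V_L = cond$V_L)),
            class = c("dimensionless_point", "power_result"))
}

#' Correlation power table over a condition grid
#'
#' Evaluates the Ne'-Re correlation over the full cross of the supplied
#' shaking frequencies, filling volumes and viscosities.
#'
#' @param n_rpm shaking frequencies (rpm)
#' @param V_L_mL filling volumes (mL)
#' @param eta_mPas dynamic viscosities (mPa s)
#' @param rho density (kg/m^3)
#' @param d maximum inner flask diameter (m)
#' @return data.frame with columns `n_rpm`, `V_L_mL`, `eta_mPas`, `Re`,
#'   `Ne_prime`, `P_W`, `PV_kW_m3`
#' @export
#' @examples
#' tab <- power_table(n_rpm = seq(180, 380, 10), V_L_mL = c(25, 40),
#'                    eta_mPas = c(1, 16))
#' max(tab$PV_kW_m3)  # rounds to 7
power_table <- function(n_rpm, V_L_mL, eta_mPas, rho = 1000, d = 0.0816) {
  grid <- expand.grid(n_rpm = n_rpm, V_L_mL = V_L_mL,
                      eta_mPas = eta_mPas, KEEP.OUT.ATTRS = FALSE)
  n <- grid$n_rpm / 60
  V <- grid$V_L_mL * 1e-6
  eta <- grid$eta_mPas * 1e-3
  Re <- rho * n * d^2 / eta
  Ne <- ne_prime(Re)
  P <- Ne * rho * n^3 * d^4 * V^(1 / 3)
  cbind(grid, Re = Re, Ne_prime = Ne, P_W = P,
        PV_kW_m3 = P / V / 1000)
}
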