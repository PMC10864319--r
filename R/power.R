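#' Squared strain-rate measure of a velocity-gradient tensor
#'
#' The scalar strain measure used in the mean-flow dissipation,
#' `2 (u_x^2 + v_y^2 + w_z^2) + (u_y + v_x)^2 + (v_z + w_y)^2 +
#' (u_z + w_x)^2`, in units of 1/s^2. Antisymmetric (rigid-rotation)
#' gradients give exactly zero; simple shear `du/dz = gd` gives `gd^2`.
#'
#' @param grad_u velocity gradients: a length-9 vector, a 3x3 matrix, or an
#'   n x 9 matrix with columns `du/dx, du/dy, du/dz, dv/dx, ..., dw/dz`
#'   (row-major rows of the tensor)
#' @return squared strain measure(s), 1/s^2
#' @export
#' @examples
#' strain_measure(c(0, 0, 100, 0, 0, 0, 0, 0, 0))  # shear 100 1/s -> 1e4
strain_measure <- function(grad_u) {
  if (is.matrix(grad_u) && all(dim(grad_u) == c(3, 3)))
    grad_u <- matrix(t(grad_u), nrow = 1)
  if (!is.matrix(grad_u)) grad_u <- matrix(grad_u, nrow = 1)
  if (ncol(grad_u) != 9) stop("grad_u must have 9 components per cell")
  if (any(!is.finite(grad_u))) stop("velocity gradients must be finite")
  ux <- grad_u[, 1]; uy <- grad_u[, 2]; uz <- grad_u[, 3]
  vx <- grad_u[, 4]; vy <- grad_u[, 5]; vz <- grad_u[, 6]
  wx <- grad_u[, 7]; wy <- grad_u[, 8]; wz <- grad_u[, 9]
  unname(2 * (ux^2 + vy^2 + wz^2) + (uy + vx)^2 + (vz + wy)^2 +
           (uz + wx)^2)
}

#' Discretised field set for dissipation integration
#'
#' Per-cell data needed to integrate the energy dissipation over the liquid
#' phase: cell volumes, liquid volume fractions, the squared strain measure
#' (or the velocity gradients it derives from), turbulent kinetic energy
#' and specific dissipation rate. Gradients are supplied, never computed
#' here: differentiating fields on unstructured meshes is solver business.
#'
#' @param volume cell volumes (m^3)
#' @param alpha liquid volume fractions in `[0, 1]`
#' @param fluid a [fluid_properties()] object
#' @param S2 squared strain measure per cell (1/s^2); alternative to
#'   `grad_u`
#' @param grad_u n x 9 velocity-gradient matrix (see [strain_measure()])
#' @param k turbulent kinetic energy (m^2/s^2)
#' @param omega specific turbulent dissipation rate (1/s)
#' @return object of class `field_set`
#' @export
field_set <- function(volume, alpha, fluid, S2 = NULL, grad_u = NULL,
                      k = 0, omega = 0) {
  stopifnot(inherits(fluid, "fluid_properties"))
  n <- length(volume)
  if (is.null(S2)) {
    if (is.null(grad_u)) stop("give either S2 or grad_u")
    S2 <- strain_measure(grad_u)
  }
  k <- rep_len(k, n); omega <- rep_len(omega, n); S2 <- rep_len(S2, n)
  if (any(volume <= 0)) stop("cell volumes must be > 0")
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12))
    stop("alpha must lie in [0, 1]")
  if (any(k < 0) || any(omega < 0) || any(S2 < 0))
    stop("k, omega and S2 must be non-negative")
  structure(list(volume = volume, alpha = pmin(pmax(alpha, 0), 1),
                 S2 = S2, k = k, omega = omega, fluid = fluid),
            class = "field_set")
}

#' Volumetric power input from the energy dissipation
#'
#' Liquid-volume-weighted mean of the local energy dissipation rate,
#' `eps = (eta/rho) * S2 + beta_star * k * omega` (W/kg), with VOF cell
#' weights `V_i * alpha_i`, split into its mean-flow and turbulent parts.
#' The power input is `P = eps * rho * V_L` and the volumetric power input
#' `P/V_L = eps * rho`.
#'
#' @param fields a [field_set()]
#' @param beta_star turbulence-model closure coefficient (default 0.09)
#' @return object of class `power_result` with `epsilon_mean`,
#'   `epsilon_turb`, `epsilon_total` (W/kg), `P` (W), `P_over_V` (W/m^3),
#'   `V_L_effective` (m^3) and `method = "dissipation"`
#' @export
epsilon_total <- function(fields, beta_star = 0.09) {
  stopifnot(inherits(fields, "field_set"))
  w <- fields$volume * fields$alpha
  V_L <- sum(w)
  if (V_L <= 0) stop("zero liquid volume: nothing to integrate over")
  fl <- fields$fluid
  nu <- fl$viscosity / fl$density
  eps_m <- sum(w * nu * fields$S2) / V_L
  eps_t <- sum(w * beta_star * fields$k * fields$omega) / V_L
  eps <- eps_m + eps_t
  structure(list(epsilon_mean = eps_m, epsilon_turb = eps_t,
                 epsilon_total = eps,
                 P = eps * fl$density * V_L,
                 P_over_V = eps * fl$density,
                 V_L_effective = V_L,
                 beta_star = beta_star,
                 method = "dissipation"),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Volumetric power input (%s)\n", x$method))
  if (x$method == "dissipation") {
    cat(sprintf("  eps = %.4g W/kg (mean %.4g + turbulent %.4g)\n",
                x$epsilon_total, x$epsilon_mean, x$epsilon_turb))
    cat(sprintf("  liquid volume %.4g mL\n", x$V_L_effective * 1e6))
  } else {
    cat(sprintf("  Re = %.4g, Ne' = %.4g\n", x$Re, x$Ne_prime))
  }
  cat(sprintf("  P = %.4g W, P/V = %.4g kW/m^3\n", x$P, x$P_over_V / 1000))
  invisible(x)
}

#' Serialise a power result to JSON
#'
#' @param x a `power_result`
#' @param file optional path
#' @return JSON string, invisibly when written
#' @export
power_result_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "power_result"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
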