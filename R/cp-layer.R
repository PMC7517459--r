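# Concentration-boundary-layer physics: the zeta <-> delta conversion,
# solution density differences, the concentration Rayleigh number and the
# convective-regime classification.

#' Polarization coefficient from boundary-layer thicknesses
#'
#' Converts concentration-boundary-layer (CBL) thicknesses into the
#' polarization coefficient
#' \deqn{\zeta = \left\{1 + RT\omega\left[\frac{\delta_l}{D_l} +
#'   \frac{\delta_h}{D_h}\right]\right\}^{-1},}
#' which reduces to \eqn{\zeta = D/(D + 2RT\omega\delta)} for symmetric
#' layers (\eqn{\delta_l = \delta_h}) and equal diffusion coefficients.
#'
#' @param omega Solute permeability \eqn{\omega_{ij}}, mol/(N s), positive.
#' @param D Diffusion coefficient(s), m^2/s: a single value used on both
#'   faces, or a length-2 vector `c(D_l, D_h)`.
#' @param delta_l,delta_h CBL thicknesses on the low- and high-concentration
#'   faces, m, non-negative. `delta_h` defaults to `delta_l` (symmetric
#'   layers).
#' @param env A [transport_environment()] supplying RT.
#' @return The polarization coefficient, in (0, 1\]; 1 when both layers have
#'   zero thickness.
#' @seealso [delta_from_zeta()] for the inverse under symmetric layers.
#' @export
zeta_from_delta <- function(omega, D, delta_l, delta_h = delta_l,
                            env = transport_environment()) {
  stopifnot(inherits(env, "transport_environment"))
  if (omega <= 0) stop("'omega' must be positive", call. = FALSE)
  D <- rep_len(as.numeric(D), 2L)
  if (any(!is.finite(D)) || any(D <= 0))
    stop("diffusion coefficients must be positive", call. = FALSE)
  if (any(delta_l < 0) || any(delta_h < 0))
    stop("layer thicknesses must be non-negative", call. = FALSE)
  1 / (1 + env$RT * omega * (delta_l / D[1L] + delta_h / D[2L]))
}

#' Boundary-layer thickness from a polarization coefficient
#'
#' Inverts the symmetric-layer form \eqn{\zeta = D/(D + 2RT\omega\delta)}:
#' \deqn{\delta = \frac{D (1 - \zeta)}{2 RT \omega \zeta}.}
#'
#' @param zeta Polarization coefficient(s) in (0, 1\]. Vectorised.
#' @param omega Solute permeability, mol/(N s), positive.
#' @param D Diffusion coefficient, m^2/s, positive.
#' @param env A [transport_environment()].
#' @return Layer thickness \eqn{\delta}, m (0 when `zeta` is 1).
#' @export
delta_from_zeta <- function(zeta, omega, D, env = transport_environment()) {
  stopifnot(inherits(env, "transport_environment"))
  if (any(!is.finite(zeta)) || any(zeta <= 0) || any(zeta > 1))
    stop("'zeta' must lie in (0, 1]", call. = FALSE)
  if (omega <= 0 || !is.finite(D) || D <= 0)
    stop("'omega' and 'D' must be positive", call. = FALSE)
  D * (1 - zeta) / (2 * env$RT * omega * zeta)
}

#' Density difference between the two chambers
#'
#' Linearised solution density difference
#' \deqn{\rho_h - \rho_l = \frac{\partial\rho}{\partial C_1}\,\Delta C_1 +
#'   \frac{\partial\rho}{\partial C_2}\,\Delta C_2}
#' from the density--concentration partials stored in the environment.
#'
#' @param dC1,dC2 Concentration differences \eqn{C_{kh} - C_{kl}}, mol/m^3.
#' @param env A [transport_environment()] with `drho_dC1`, `drho_dC2` set.
#' @return Density difference, kg/m^3.
#' @export
density_difference <- function(dC1, dC2, env) {
  stopifnot(inherits(env, "transport_environment"))
  if (!is.finite(env$drho_dC1) || !is.finite(env$drho_dC2))
    stop("environment lacks density-concentration partials", call. = FALSE)
  env$drho_dC1 * dC1 + env$drho_dC2 * dC2
}

#' Concentration Rayleigh number
#'
#' Buoyancy criterion for onset of free convection in the CBL complex,
#' \deqn{R_C = \frac{g\,(\rho_h - \rho_l)\,\delta^3}{\rho\,\nu\,D_{11}}.}
#' Cubic in the layer thickness and linear in the density difference, whose
#' sign it inherits.
#'
#' @param delta_rho Density difference \eqn{\rho_h - \rho_l}, kg/m^3.
#' @param delta CBL thickness, m, non-negative.
#' @param env A [transport_environment()] with `rho_ref`, `nu` and `D[1,1]`.
#' @return The dimensionless Rayleigh number.
#' @export
rayleigh_number <- function(delta_rho, delta, env) {
  stopifnot(inherits(env, "transport_environment"))
  if (any(delta < 0)) stop("'delta' must be non-negative", call. = FALSE)
  D11 <- env$D[1L, 1L]
  if (!is.finite(env$rho_ref) || env$rho_ref <= 0 ||
      !is.finite(env$nu) || env$nu <= 0 || !is.finite(D11) || D11 <= 0)
    stop("environment must supply positive rho_ref, nu and D11", call. = FALSE)
  env$g * delta_rho * delta^3 / (env$rho_ref * env$nu * D11)
}

#' Classify the convective regime of a membrane configuration
#'
#' The hydrodynamic stability of the CBL complex depends on the membrane
#' orientation and on where the chamber density difference sits relative to
#' the critical density difference at which both configurations behave
#' identically. Below the critical value the CBL complex in Configuration A
#' (dilute solution on top) is unstable and drives free convection while
#' Configuration B is stable; above it the roles swap. Within `tolerance` of
#' the critical value the system sits at the critical (configuration
#' independent) state.
#'
#' @param configuration `"A"` or `"B"`.
#' @param delta_rho Chamber density difference \eqn{\rho_h - \rho_l}, kg/m^3.
#' @param rayleigh Optional concentration Rayleigh number to report alongside
#'   the classification.
#' @param rayleigh_crit Critical Rayleigh number for rigid--free boundaries
#'   (reported as a secondary indicator).
#' @param delta_rho_crit Critical density difference, kg/m^3.
#' @param tolerance Absolute tolerance on `delta_rho - delta_rho_crit` for
#'   declaring the critical state, kg/m^3.
#' @return An object of class `convection_assessment`: a list with
#'   `configuration`, `delta_rho`, `rayleigh`, `rayleigh_crit`,
#'   `rayleigh_supercritical` and `regime` (one of
#'   `"stable_nonconvective"`, `"unstable_convective"`, `"critical"`).
#' @export
classify_convection <- function(configuration, delta_rho,
                                rayleigh = NA_real_,
                                rayleigh_crit = 1100.6,
                                delta_rho_crit = 0.046,
                                tolerance = 1e-3) {
  if (!is.character(configuration) ||
      !configuration %in% c("A", "B"))
    stop("unknown configuration label: ", configuration, call. = FALSE)
  regime <- if (abs(delta_rho - delta_rho_crit) <= tolerance) {
    "critical"
  } else if (delta_rho < delta_rho_crit) {
    if (configuration == "A") "unstable_convective" else "stable_nonconvective"
  } else {
    if (configuration == "A") "stable_nonconvective" else "unstable_convective"
  }
  structure(
    list(configuration = configuration, delta_rho = delta_rho,
         rayleigh = rayleigh, rayleigh_crit = rayleigh_crit,
         rayleigh_supercritical =
           if (is.finite(rayleigh)) abs(rayleigh) > rayleigh_crit else NA,
         regime = regime),
    class = "convection_assessment")
}

#' @export
print.convection_assessment <- function(x, ...) {
  cat(sprintf("Configuration %s: %s (delta_rho = %.4g kg/m^3", x$configuration,
              x$regime, x$delta_rho))
  if (is.finite(x$rayleigh))
    cat(sprintf(", R_C = %.4g vs crit %.4g", x$rayleigh, x$rayleigh_crit))
  cat(")\n")
  invisible(x)
}

#' @export
format.convection_assessment <- function(x, ...) x$regime

as_json_list <- function(x) UseMethod("as_json_list")

#' @export
as_json_list.convection_assessment <- function(x) {
  list(configuration = x$configuration, delta_rho = x$delta_rho,
       rayleigh = x$rayleigh, rayleigh_crit = x$rayleigh_crit,
       regime = x$regime)
}
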