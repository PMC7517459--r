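# Forward Kedem-Katchalsky flux equations for ternary non-electrolyte
# solutions under concentration polarization, and the thermodynamic forces
# conjugate to the fluxes in the resistance representation.

#' Thermodynamic forces from bath state
#'
#' The force vector conjugate to \eqn{(J_v, J_1, J_2)} in the resistance
#' representation:
#' \deqn{X_1 = \Delta P - \Delta\pi_1 - \Delta\pi_2, \quad
#'   X_2 = \Delta\pi_1 / \bar{C}_1, \quad X_3 = \Delta\pi_2 / \bar{C}_2.}
#' Because \eqn{\bar{C}} is the log-mean, \eqn{\Delta\pi_k/\bar{C}_k =
#' RT\,\ln(C_{kh}/C_{kl})} identically.
#'
#' @param baths A [bath_state()].
#' @param env A [transport_environment()].
#' @return Named numeric vector `c(X1 = , X2 = , X3 = )`, units Pa, J/mol,
#'   J/mol.
#' @export
forces_from_baths <- function(baths, env = transport_environment()) {
  stopifnot(inherits(baths, "bath_state"))
  dpi1 <- osmotic_pressure_difference(baths$C1h, baths$C1l, env)
  dpi2 <- osmotic_pressure_difference(baths$C2h, baths$C2l, env)
  c(X1 = baths$dP - dpi1 - dpi2,
    X2 = dpi1 / baths$c1bar,
    X3 = dpi2 / baths$c2bar)
}

#' Kedem-Katchalsky fluxes under concentration polarization
#'
#' Evaluates the modified Kedem--Katchalsky equations for a ternary
#' non-electrolyte solution:
#' \deqn{J_v = \zeta_p L_p (\Delta P - \zeta_{v1}\sigma_1\Delta\pi_1 -
#'   \zeta_{v2}\sigma_2\Delta\pi_2)}
#' \deqn{J_1 = \zeta_{s11}\omega_{11}\Delta\pi_1 +
#'   \zeta_{s12}\omega_{12}\Delta\pi_2 + \bar{C}_1(1 -
#'   \zeta_{a1}\sigma_1)J_v}
#' \deqn{J_2 = \zeta_{s21}\omega_{21}\Delta\pi_1 +
#'   \zeta_{s22}\omega_{22}\Delta\pi_2 + \bar{C}_2(1 -
#'   \zeta_{a2}\sigma_2)J_v}
#' With all polarization coefficients equal to 1 these are the classical
#' equations for stirred solutions.
#'
#' The advective term of \eqn{J_2} uses \eqn{\bar{C}_2} by default, the form
#' consistent with the resistance-matrix coefficients and with exact
#' inversion; `advective = "as_printed"` substitutes \eqn{\bar{C}_1}, a
#' variant retained for auditing the source formulas.
#'
#' @param membrane A [membrane_coefficients()].
#' @param cp A [cp_coefficients()] set.
#' @param baths A [bath_state()].
#' @param env A [transport_environment()].
#' @param advective `"c2bar"` (default) or `"as_printed"`.
#' @return An object of class `flux_vector`: named list with `Jv` (m/s),
#'   `J1`, `J2` (mol/(m^2 s)) and the `configuration` label.
#' @export
kk_fluxes <- function(membrane, cp, baths, env = transport_environment(),
                      advective = c("c2bar", "as_printed")) {
  stopifnot(inherits(membrane, "membrane_coefficients"),
            inherits(cp, "cp_coefficients"),
            inherits(baths, "bath_state"))
  advective <- match.arg(advective)
  dpi1 <- osmotic_pressure_difference(baths$C1h, baths$C1l, env)
  dpi2 <- osmotic_pressure_difference(baths$C2h, baths$C2l, env)
  om <- membrane$omega
  Jv <- cp$zeta_p * membrane$Lp *
    (baths$dP - cp$zeta_v1 * membrane$sigma1 * dpi1 -
       cp$zeta_v2 * membrane$sigma2 * dpi2)
  J1 <- cp$zeta_s11 * om[1, 1] * dpi1 + cp$zeta_s12 * om[1, 2] * dpi2 +
    baths$c1bar * (1 - cp$zeta_a1 * membrane$sigma1) * Jv
  c2_adv <- if (advective == "c2bar") baths$c2bar else baths$c1bar
  J2 <- cp$zeta_s21 * om[2, 1] * dpi1 + cp$zeta_s22 * om[2, 2] * dpi2 +
    c2_adv * (1 - cp$zeta_a2 * membrane$sigma2) * Jv
  structure(list(Jv = Jv, J1 = J1, J2 = J2,
                 configuration = cp$configuration),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat(sprintf("Fluxes (%s): Jv = %.4g m/s, J1 = %.4g, J2 = %.4g mol/(m^2 s)\n",
              x$configuration, x$Jv, x$J1, x$J2))
  invisible(x)
}

#' Fluxes as a linear map of the resistance-representation forces
#'
#' Evaluates the same flux equations as [kk_fluxes()] but parameterised by
#' the force vector \eqn{(X_1, X_2, X_3)} and the mean concentrations,
#' using \eqn{\Delta P = X_1 + \bar{C}_1 X_2 + \bar{C}_2 X_3},
#' \eqn{\Delta\pi_k = \bar{C}_k X_k}. This exposes the conductance map whose
#' inverse is the resistance matrix, and is the workhorse of the numerical
#' inversion oracle.
#'
#' @param membrane A [membrane_coefficients()].
#' @param cp A [cp_coefficients()].
#' @param X Numeric length-3 force vector `(X1, X2, X3)`.
#' @param c1bar,c2bar Mean (log-mean) solute concentrations, mol/m^3.
#' @return Numeric length-3 flux vector `(Jv, J1, J2)`.
#' @export
kk_fluxes_from_forces <- function(membrane, cp, X, c1bar, c2bar) {
  stopifnot(inherits(membrane, "membrane_coefficients"),
            inherits(cp, "cp_coefficients"), length(X) == 3L)
  om <- membrane$omega
  dP <- X[1L] + c1bar * X[2L] + c2bar * X[3L]
  dpi1 <- c1bar * X[2L]
  dpi2 <- c2bar * X[3L]
  Jv <- cp$zeta_p * membrane$Lp *
    (dP - cp$zeta_v1 * membrane$sigma1 * dpi1 -
       cp$zeta_v2 * membrane$sigma2 * dpi2)
  J1 <- cp$zeta_s11 * om[1, 1] * dpi1 + cp$zeta_s12 * om[1, 2] * dpi2 +
    c1bar * (1 - cp$zeta_a1 * membrane$sigma1) * Jv
  J2 <- cp$zeta_s21 * om[2, 1] * dpi1 + cp$zeta_s22 * om[2, 2] * dpi2 +
    c2bar * (1 - cp$zeta_a2 * membrane$sigma2) * Jv
  c(Jv = unname(Jv), J1 = unname(J1), J2 = unname(J2))
}
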