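# Domain types and constants shared by every other module: membrane practical
# coefficients, bath state, environment constants, concentration-polarization
# coefficient sets, and the published Nephrophan/glucose/ethanol parameter set.

#' Membrane practical transport coefficients
#'
#' Bundles the Kedem--Katchalsky "practical" coefficients that characterise a
#' membrane as a black box for a ternary non-electrolyte solution: the
#' hydraulic permeability \eqn{L_p}, the reflection coefficients
#' \eqn{\sigma_1, \sigma_2} of the two solutes, and the 2x2 solute
#' permeability matrix \eqn{\omega_{kf}} whose off-diagonal entries are the
#' cross-permeabilities (flux of solute k driven by the osmotic force of
#' solute f).
#'
#' @param Lp Hydraulic permeability, m^3/(N s). Must be positive.
#' @param sigma1,sigma2 Reflection coefficients of solutes 1 and 2,
#'   dimensionless, in \[0, 1\].
#' @param omega11,omega12,omega21,omega22 Solute permeability coefficients,
#'   mol/(N s). Diagonal entries must be positive and the permeability
#'   determinant \eqn{\gamma = \omega_{11}\omega_{22} -
#'   \omega_{12}\omega_{21}} must be nonzero.
#'
#' @return An object of class `membrane_coefficients`.
#' @seealso [nephrophan_fixture()] for the published Nephrophan values.
#' @export
#' @examples
#' m <- membrane_coefficients(Lp = 4.9e-12, sigma1 = 0.068, sigma2 = 0.025,
#'                            omega11 = 0.8e-9, omega12 = 0.81e-13,
#'                            omega21 = 1.63e-12, omega22 = 1.43e-9)
#' permeability_determinant(m)
membrane_coefficients <- function(Lp, sigma1, sigma2,
                                  omega11, omega12, omega21, omega22) {
  stopifnot(is.numeric(Lp), length(Lp) == 1L)
  if (Lp <= 0) stop("'Lp' must be positive", call. = FALSE)
  for (s in c(sigma1, sigma2)) {
    if (!is.finite(s) || s < 0 || s > 1)
      stop("reflection coefficients must lie in [0, 1]", call. = FALSE)
  }
  if (omega11 <= 0 || omega22 <= 0)
    stop("diagonal solute permeabilities 'omega11', 'omega22' must be positive",
         call. = FALSE)
  gamma <- omega11 * omega22 - omega12 * omega21
  if (gamma == 0)
    stop("permeability determinant omega11*omega22 - omega12*omega21 is zero",
         call. = FALSE)
  structure(
    list(Lp = Lp, sigma1 = sigma1, sigma2 = sigma2,
         omega = matrix(c(omega11, omega12, omega21, omega22), 2L, 2L,
                        byrow = TRUE,
                        dimnames = list(c("1", "2"), c("1", "2")))),
    class = "membrane_coefficients")
}

#' @export
print.membrane_coefficients <- function(x, ...) {
  cat("Membrane practical coefficients\n")
  cat(sprintf("  Lp     = %.4g m^3/(N s)\n", x$Lp))
  cat(sprintf("  sigma  = (%.4g, %.4g)\n", x$sigma1, x$sigma2))
  cat(sprintf("  omega  = [%.4g %.4g; %.4g %.4g] mol/(N s)\n",
              x$omega[1, 1], x$omega[1, 2], x$omega[2, 1], x$omega[2, 2]))
  invisible(x)
}

#' Permeability determinant of a membrane
#'
#' The determinant \eqn{\gamma = \omega_{11}\omega_{22} -
#' \omega_{12}\omega_{21}} of the solute permeability matrix. Its sign fixes
#' the sign of the resistance-matrix determinant.
#'
#' @param membrane A [membrane_coefficients()] object.
#' @return The determinant, (mol/(N s))^2.
#' @export
permeability_determinant <- function(membrane) {
  stopifnot(inherits(membrane, "membrane_coefficients"))
  membrane$omega[1, 1] * membrane$omega[2, 2] -
    membrane$omega[1, 2] * membrane$omega[2, 1]
}

#' Environment constants for transport calculations
#'
#' Physical constants and solution properties used across the package:
#' gas constant and temperature (whose product RT converts concentration
#' differences to osmotic pressures), gravitational acceleration, kinematic
#' viscosity, reference density, density--concentration partial derivatives
#' and the solute diffusion coefficients.
#'
#' @param temperature Absolute temperature, K.
#' @param R_gas Gas constant, J/(mol K).
#' @param g Gravitational acceleration, m/s^2.
#' @param nu Kinematic viscosity of the solution, m^2/s.
#' @param rho_ref Reference solution density, kg/m^3.
#' @param drho_dC1,drho_dC2 Partial derivatives of solution density with
#'   respect to the two solute concentrations, kg/mol.
#' @param D 2x2 matrix of diffusion coefficients \eqn{D_{ij}}, m^2/s. Entries
#'   that are not needed may be left `NA`; operations requiring them check.
#'
#' @return An object of class `transport_environment` with an `RT` element
#'   (J/mol per unit concentration, i.e. Pa m^3/mol).
#' @export
transport_environment <- function(temperature = 298.15, R_gas = 8.314,
                                  g = 9.81, nu = NA_real_,
                                  rho_ref = NA_real_,
                                  drho_dC1 = NA_real_, drho_dC2 = NA_real_,
                                  D = matrix(NA_real_, 2L, 2L)) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be positive", call. = FALSE)
  if (g < 0) stop("'g' must be non-negative", call. = FALSE)
  if (is.finite(nu) && nu <= 0) stop("'nu' must be positive", call. = FALSE)
  if (is.finite(rho_ref) && rho_ref <= 0)
    stop("'rho_ref' must be positive", call. = FALSE)
  D <- matrix(as.numeric(D), 2L, 2L)
  if (any(is.finite(diag(D)) & diag(D) <= 0))
    stop("diagonal diffusion coefficients must be positive", call. = FALSE)
  structure(
    list(temperature = temperature, R_gas = R_gas, RT = R_gas * temperature,
         g = g, nu = nu, rho_ref = rho_ref,
         drho_dC1 = drho_dC1, drho_dC2 = drho_dC2, D = D),
    class = "transport_environment")
}

#' Bath (chamber) state of a two-solute membrane system
#'
#' Concentrations of both solutes in the high- and low-concentration chambers
#' and the hydrostatic pressure difference across the membrane.
#'
#' @param C1h,C1l Solute 1 concentrations in chambers h and l, mol/m^3.
#' @param C2h,C2l Solute 2 concentrations in chambers h and l, mol/m^3.
#' @param dP Hydrostatic pressure difference \eqn{\Delta P = P_h - P_l}, Pa.
#'
#' @return An object of class `bath_state` carrying the four concentrations,
#'   `dP`, and the derived log-mean concentrations `c1bar`, `c2bar`.
#' @export
bath_state <- function(C1h, C1l, C2h, C2l, dP = 0) {
  conc <- c(C1h = C1h, C1l = C1l, C2h = C2h, C2l = C2l)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all bath concentrations must be positive and finite", call. = FALSE)
  if (C1h < C1l || C2h < C2l)
    stop("chamber h must hold the higher (or equal) concentration",
         call. = FALSE)
  structure(
    list(C1h = C1h, C1l = C1l, C2h = C2h, C2l = C2l, dP = dP,
         c1bar = log_mean_concentration(C1h, C1l),
         c2bar = log_mean_concentration(C2h, C2l)),
    class = "bath_state")
}

#' @export
print.bath_state <- function(x, ...) {
  cat("Bath state\n")
  cat(sprintf("  solute 1: Ch = %g, Cl = %g  (log-mean %.4g) mol/m^3\n",
              x$C1h, x$C1l, x$c1bar))
  cat(sprintf("  solute 2: Ch = %g, Cl = %g  (log-mean %.4g) mol/m^3\n",
              x$C2h, x$C2l, x$c2bar))
  cat(sprintf("  dP = %g Pa\n", x$dP))
  invisible(x)
}

#' Log-mean concentration
#'
#' The mean intramembrane concentration \eqn{\bar{C} = (C_h - C_l) /
#' \ln(C_h / C_l)} used throughout the Kedem--Katchalsky formalism. At
#' \eqn{C_h = C_l} the continuous limit \eqn{\bar{C} = C} is returned.
#'
#' @param Ch,Cl Concentrations, mol/m^3, both positive. Vectorised.
#' @return Log-mean concentration(s), mol/m^3; always between `min(Ch, Cl)`
#'   and the arithmetic mean.
#' @export
#' @examples
#' log_mean_concentration(33.44, 1)  # 9.24
#' log_mean_concentration(201, 1)    # 37.71
log_mean_concentration <- function(Ch, Cl) {
  if (any(!is.finite(Ch)) || any(!is.finite(Cl)) || any(Ch <= 0) || any(Cl <= 0))
    stop("concentrations must be positive and finite", call. = FALSE)
  out <- ifelse(Ch == Cl, Ch, (Ch - Cl) / log(Ch / Cl))
  as.numeric(out)
}

#' Osmotic pressure difference of one solute
#'
#' Van 't Hoff osmotic pressure difference \eqn{\Delta\pi = RT (C_h - C_l)}.
#'
#' @param Ch,Cl Concentrations, mol/m^3. Vectorised.
#' @param env A [transport_environment()] supplying RT.
#' @return Pressure difference, Pa.
#' @export
osmotic_pressure_difference <- function(Ch, Cl, env = transport_environment()) {
  stopifnot(inherits(env, "transport_environment"))
  env$RT * (Ch - Cl)
}

#' Concentration-polarization coefficient set
#'
#' The nine dimensionless coefficients \eqn{\zeta \in (0, 1]} that attenuate
#' the membrane practical coefficients when concentration boundary layers are
#' present: hydraulic (`zeta_p`), osmotic (`zeta_v1`, `zeta_v2`), advective
#' (`zeta_a1`, `zeta_a2`) and diffusive (`zeta_s11`, `zeta_s12`, `zeta_s21`,
#' `zeta_s22`) polarization. All equal to 1 means perfectly stirred
#' (homogeneous) solutions.
#'
#' @param zeta_p,zeta_v1,zeta_v2,zeta_a1,zeta_a2 Hydraulic, osmotic and
#'   advective polarization coefficients, each in (0, 1\].
#' @param zeta_s11,zeta_s12,zeta_s21,zeta_s22 Diffusive polarization
#'   coefficients, each in (0, 1\].
#' @param configuration Orientation label of the horizontal membrane system:
#'   `"A"` (dilute solution above the membrane), `"B"` (reversed), or
#'   `"homogeneous"`.
#'
#' @return An object of class `cp_coefficients`.
#' @seealso [cp_homogeneous()], [cp_reduced()]
#' @export
cp_coefficients <- function(zeta_p = 1, zeta_v1 = 1, zeta_v2 = 1,
                            zeta_a1 = 1, zeta_a2 = 1,
                            zeta_s11 = 1, zeta_s12 = 1,
                            zeta_s21 = 1, zeta_s22 = 1,
                            configuration = c("A", "B", "homogeneous")) {
  configuration <- match.arg(configuration)
  z <- c(zeta_p = zeta_p, zeta_v1 = zeta_v1, zeta_v2 = zeta_v2,
         zeta_a1 = zeta_a1, zeta_a2 = zeta_a2,
         zeta_s11 = zeta_s11, zeta_s12 = zeta_s12,
         zeta_s21 = zeta_s21, zeta_s22 = zeta_s22)
  if (any(!is.finite(z)) || any(z <= 0) || any(z > 1))
    stop("all polarization coefficients must lie in (0, 1]", call. = FALSE)
  structure(c(as.list(z), list(configuration = configuration)),
            class = "cp_coefficients")
}

#' Homogeneous (perfectly stirred) polarization coefficients
#'
#' All nine polarization coefficients set to exactly 1, recovering the
#' classical Kedem--Katchalsky equations for stirred solutions.
#'
#' @return A `cp_coefficients` object with configuration `"homogeneous"`.
#' @export
cp_homogeneous <- function() {
  cp_coefficients(configuration = "homogeneous")
}

#' Reduced polarization coefficient set
#'
#' The empirically supported reduction for the Nephrophan/glucose/ethanol
#' system: hydraulic and advective polarization are absent
#' (\eqn{\zeta_p = \zeta_{a1} = \zeta_{a2} = 1}) and each solute shares one
#' coefficient across its osmotic and diffusive entries
#' (\eqn{\zeta_{v1} = \zeta_{s11} = \zeta_{s12} = \zeta_1},
#' \eqn{\zeta_{v2} = \zeta_{s22} = \zeta_{s21} = \zeta_2}).
#'
#' @param zeta1,zeta2 Per-solute polarization coefficients in (0, 1\].
#' @param configuration `"A"` or `"B"`.
#' @return A `cp_coefficients` object.
#' @export
cp_reduced <- function(zeta1, zeta2 = zeta1, configuration = c("A", "B")) {
  configuration <- match.arg(configuration)
  cp_coefficients(zeta_p = 1, zeta_v1 = zeta1, zeta_v2 = zeta2,
                  zeta_a1 = 1, zeta_a2 = 1,
                  zeta_s11 = zeta1, zeta_s12 = zeta1,
                  zeta_s21 = zeta2, zeta_s22 = zeta2,
                  configuration = configuration)
}

#' Published Nephrophan/glucose/ethanol parameter set
#'
#' The full parameter set for the Nephrophan cellulose-acetate membrane
#' bathed by glucose (solute 1) in aqueous ethanol (solute 2): membrane
#' practical coefficients, environment constants, and the bath
#' concentrations. The glucose bath concentration `C1h` is the studied
#' variable (1 to 101 mol/m^3); ethanol is fixed at `C2h` = 201 mol/m^3 and
#' both chamber-l concentrations at 1 mol/m^3.
#'
#' Only the glucose self-diffusion coefficient D11 was reported; the other
#' diffusion entries are left `NA` and operations that need them require
#' explicit values.
#'
#' @param C1h Glucose concentration in chamber h, mol/m^3 (default 33.44,
#'   the value whose log-mean with 1 mol/m^3 is 9.24 mol/m^3).
#' @param temperature Absolute temperature, K (not reported with the data
#'   set; defaults to 298.15 K).
#' @return A list with elements `membrane`, `environment` and `baths`.
#' @export
#' @examples
#' fx <- nephrophan_fixture()
#' fx$membrane$Lp
#' fx$baths$c1bar
nephrophan_fixture <- function(C1h = 33.44, temperature = 298.15) {
  if (C1h < 1 || C1h > 101)
    stop("'C1h' outside the studied range [1, 101] mol/m^3", call. = FALSE)
  list(
    membrane = membrane_coefficients(
      Lp = 4.9e-12, sigma1 = 0.068, sigma2 = 0.025,
      omega11 = 0.8e-9, omega12 = 0.81e-13,
      omega21 = 1.63e-12, omega22 = 1.43e-9),
    environment = transport_environment(
      temperature = temperature, g = 9.81, nu = 1.063e-6, rho_ref = 998.3,
      drho_dC1 = 0.06, drho_dC2 = -0.0095,
      D = matrix(c(0.69e-9, NA, NA, NA), 2L, 2L, byrow = TRUE)),
    baths = bath_state(C1h = C1h, C1l = 1, C2h = 201, C2l = 1, dP = 0)
  )
}
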