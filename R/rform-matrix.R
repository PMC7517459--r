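# The 3x3 resistance (Peusner R-form) matrix of the Kedem-Katchalsky
# equations for ternary solutions under concentration polarization, its
# determinant, and a numerical-inversion oracle.
#
# Two variants are carried side by side. "as_printed" reproduces the source
# coefficient formulas verbatim (with the cross-permeability factor omega21
# restored in R31, which dimensional analysis requires). "strict_inverse"
# additionally divides R21 by c1bar and R31 by c2bar; this is the variant
# that exactly inverts the conductance map implied by the flux equations,
# is dimensionally consistent row by row, and is the default for
# determinants, coupling and energy statistics.

kkp_singularity_error <- function(message) {
  structure(class = c("kkp_singularity_error", "error", "condition"),
            list(message = message, call = NULL))
}

#' Resistance-matrix (Peusner R-form) coefficients
#'
#' Builds the 3x3 matrix \eqn{R_{ij}} relating the thermodynamic forces
#' \eqn{(\Delta P - \Delta\pi_1 - \Delta\pi_2,\; \Delta\pi_1/\bar{C}_1,\;
#' \Delta\pi_2/\bar{C}_2)} to the fluxes \eqn{(J_v, J_1, J_2)} under
#' concentration polarization. With all polarization coefficients equal to 1
#' the entries collapse to the homogeneous-solution coefficients.
#'
#' The closed forms use the zeta-weighted permeability determinant
#' \eqn{\gamma_\zeta = \zeta_{s11}\omega_{11}\,\zeta_{s22}\omega_{22} -
#' \zeta_{s12}\omega_{12}\,\zeta_{s21}\omega_{21}}, which must be nonzero.
#'
#' @param membrane A [membrane_coefficients()].
#' @param cp A [cp_coefficients()] set; defaults to homogeneous.
#' @param c1bar,c2bar Mean (log-mean) solute concentrations, mol/m^3.
#' @param variant `"strict_inverse"` (default; the exact inverse of the
#'   conductance map) or `"as_printed"` (source formulas, whose rows 2-3
#'   first-column entries carry an extra concentration factor).
#' @return An object of class `rform_matrix`: list with `entries` (3x3,
#'   dimnames v/1/2), `variant`, `configuration`, `gamma_zeta`, `c1bar`,
#'   `c2bar` and `det` (see [rform_determinant()]).
#' @export
#' @examples
#' fx <- nephrophan_fixture()
#' rform_matrix(fx$membrane, cp_homogeneous(), c1bar = 1.44, c2bar = 37.71)
rform_matrix <- function(membrane, cp = cp_homogeneous(), c1bar, c2bar,
                         variant = c("strict_inverse", "as_printed")) {
  stopifnot(inherits(membrane, "membrane_coefficients"),
            inherits(cp, "cp_coefficients"))
  variant <- match.arg(variant)
  if (!is.finite(c1bar) || c1bar <= 0 || !is.finite(c2bar) || c2bar <= 0)
    stop("mean concentrations must be positive", call. = FALSE)
  om <- membrane$omega
  s1 <- membrane$sigma1; s2 <- membrane$sigma2
  w11 <- cp$zeta_s11 * om[1, 1]; w12 <- cp$zeta_s12 * om[1, 2]
  w21 <- cp$zeta_s21 * om[2, 1]; w22 <- cp$zeta_s22 * om[2, 2]
  gamma <- w11 * w22 - w12 * w21
  if (abs(gamma) < 1e-30)
    stop(kkp_singularity_error(paste0(
      "singular permeability determinant: the condition ",
      "omega11*zeta_s11*omega22*zeta_s22 != omega12*zeta_s12*omega21*zeta_s21",
      " is violated")))
  a1 <- w12 * (1 - cp$zeta_a2 * s2) * c2bar
  a2 <- w22 * (1 - cp$zeta_a1 * s1) * c1bar
  a3 <- w21 * (1 - cp$zeta_a1 * s1) * c1bar
  a4 <- w11 * (1 - cp$zeta_a2 * s2) * c2bar
  v1 <- 1 - cp$zeta_v1 * s1
  v2 <- 1 - cp$zeta_v2 * s2

  R11 <- 1 / (cp$zeta_p * membrane$Lp) -
    (v1 * (a1 - a2) + v2 * (a3 - a4)) / gamma
  R12 <- (w21 * v2 - w22 * v1) / gamma
  R13 <- (w12 * v1 - w11 * v2) / gamma
  R21 <- (a1 - a2) / gamma
  R22 <- w22 / (gamma * c1bar)
  R23 <- -w12 / (gamma * c1bar)
  R31 <- (a3 - a4) / gamma
  R32 <- -w21 / (gamma * c2bar)
  R33 <- w11 / (gamma * c2bar)
  if (variant == "strict_inverse") {
    R21 <- R21 / c1bar
    R31 <- R31 / c2bar
  }
  entries <- matrix(c(R11, R12, R13, R21, R22, R23, R31, R32, R33),
                    3L, 3L, byrow = TRUE,
                    dimnames = list(c("v", "1", "2"), c("v", "1", "2")))
  det_strict <- 1 / (cp$zeta_p * membrane$Lp * c1bar * c2bar * gamma)
  structure(
    list(entries = entries, variant = variant,
         configuration = cp$configuration, gamma_zeta = gamma,
         c1bar = c1bar, c2bar = c2bar,
         det = if (variant == "strict_inverse") det_strict else det(entries)),
    class = "rform_matrix")
}

#' @export
print.rform_matrix <- function(x, ...) {
  cat(sprintf("Resistance matrix (%s, %s), det = %.6g m^3 N^3 s^3/mol^4\n",
              x$configuration, x$variant, x$det))
  print(signif(x$entries, 6))
  invisible(x)
}

#' Determinant of the resistance matrix
#'
#' For the strict-inverse variant the determinant has the closed form
#' \deqn{\det R = \left[\zeta_p L_p\,\bar{C}_1 \bar{C}_2\,
#'   \gamma_\zeta\right]^{-1},}
#' positive iff the zeta-weighted permeability determinant
#' \eqn{\gamma_\zeta} is positive. For the as-printed variant the direct 3x3
#' determinant of the stored entries is returned.
#'
#' @param matrix An [rform_matrix()] object.
#' @return Determinant, m^3 N^3 s^3 / mol^4 (strict variant).
#' @export
rform_determinant <- function(matrix) {
  stopifnot(inherits(matrix, "rform_matrix"))
  matrix$det
}

#' Numerical inversion oracle for the resistance matrix
#'
#' Independently reconstructs the resistance matrix by brute force: builds
#' the conductance map \eqn{(J_v, J_1, J_2) = L (X_1, X_2, X_3)}
#' column-by-column from [kk_fluxes_from_forces()] evaluated at unit forces,
#' then inverts it numerically. Used to validate the closed-form
#' `strict_inverse` entries.
#'
#' @param membrane A [membrane_coefficients()].
#' @param cp A [cp_coefficients()].
#' @param baths A [bath_state()] (only the mean concentrations are used).
#' @param env A [transport_environment()] (accepted for interface symmetry;
#'   the conductance map depends on forces, not on RT).
#' @return A 3x3 numeric matrix, the numerical inverse of the conductance
#'   map.
#' @export
invert_conductance_oracle <- function(membrane, cp, baths,
                                      env = transport_environment()) {
  stopifnot(inherits(baths, "bath_state"))
  L <- vapply(seq_len(3L), function(j) {
    X <- numeric(3L); X[j] <- 1
    kk_fluxes_from_forces(membrane, cp, X, baths$c1bar, baths$c2bar)
  }, numeric(3L))
  kappa <- kappa(L, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e15)
    stop(kkp_singularity_error(sprintf(
      "conductance map numerically singular (condition number %.3g)", kappa)))
  solve(L)
}
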