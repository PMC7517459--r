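# Configuration-difference diagnostics: the xi coefficients comparing the
# resistance matrices of the two gravity configurations against the
# homogeneous matrix, their simplified closed forms for the reduced
# polarization model, and the sign-criteria classification of natural
# convection effects.
#
# The authoritative definition is the matrix form (xi_ij = (R_ij^A -
# R_ij^B)/R_ij, computed from actual matrices). The simplified closed forms
# are documented approximations carried with the signs of their source
# formulas, which for several entries conflict with the matrix form (the
# magnitudes agree); see the methods vignette.

xi_entry_names <- c("11", "12", "13", "21", "22", "23", "31", "32", "33")

xi_interpret <- function(xi, tol) {
  ifelse(is.na(xi), NA_character_,
         ifelse(abs(xi) <= tol, "critical",
                ifelse(xi < 0, "convection_up", "convection_down")))
}

xi_sign <- function(xi, tol) {
  ifelse(is.na(xi), NA_character_,
         ifelse(abs(xi) <= tol, "zero",
                ifelse(xi < 0, "negative", "positive")))
}

new_xi_summary <- function(xi, xi_det, tol, source) {
  signs <- matrix(xi_sign(xi, tol), 3L, 3L, dimnames = dimnames(xi))
  interpretation <- matrix(xi_interpret(xi, tol), 3L, 3L,
                           dimnames = dimnames(xi))
  structure(list(xi = xi, xi_det = xi_det, signs = signs,
                 interpretation = interpretation,
                 zero_tolerance = tol, source = source),
            class = "xi_summary")
}

#' Configuration-difference coefficients xi
#'
#' Entrywise comparison of the resistance matrices of Configurations A and B
#' against the homogeneous matrix,
#' \deqn{\xi_{ij} = \frac{R_{ij}^A - R_{ij}^B}{R_{ij}}, \qquad
#'   \xi_{det} = \frac{R_{det}^A - R_{det}^B}{R_{det}}.}
#' These dimensionless coefficients measure the distance of the system from
#' the critical (non-convective) state: \eqn{\xi < 0} indicates free
#' convection directed vertically upwards, \eqn{\xi > 0} downwards, and
#' \eqn{\xi = 0} the critical state. Swapping A and B negates every entry.
#'
#' @param R_A,R_B,R_hom [rform_matrix()] objects for Configurations A, B and
#'   the homogeneous case, sharing the same variant.
#' @param zero_tolerance Absolute tolerance below which an entry is classed
#'   as zero/critical.
#' @return An object of class `xi_summary`: `xi` (3x3), `xi_det`, `signs`
#'   and `interpretation` matrices (`"convection_up"`, `"critical"`,
#'   `"convection_down"`). Entries with a zero homogeneous denominator are
#'   `NA` (flagged, not an error).
#' @export
xi_coefficients <- function(R_A, R_B, R_hom, zero_tolerance = 1e-3) {
  stopifnot(inherits(R_A, "rform_matrix"), inherits(R_B, "rform_matrix"),
            inherits(R_hom, "rform_matrix"))
  if (R_A$variant != R_B$variant || R_A$variant != R_hom$variant)
    stop("all three matrices must share the same variant", call. = FALSE)
  denom <- R_hom$entries
  xi <- (R_A$entries - R_B$entries) / denom
  xi[denom == 0] <- NA_real_
  xi_det <- if (R_hom$det == 0) NA_real_ else (R_A$det - R_B$det) / R_hom$det
  new_xi_summary(xi, xi_det, zero_tolerance, source = "matrix")
}

#' @export
print.xi_summary <- function(x, ...) {
  cat(sprintf("xi summary (%s form), xi_det = %.6g\n", x$source, x$xi_det))
  print(signif(x$xi, 6))
  invisible(x)
}

#' Simplified closed forms of the xi coefficients
#'
#' Closed-form approximations of [xi_coefficients()] valid for the reduced
#' polarization model (no hydraulic/advective polarization, one shared
#' \eqn{\zeta} per configuration) and negligible cross-permeabilities. With
#' \eqn{f = (\zeta^A - \zeta^B)/(\zeta^A \zeta^B)}:
#' \deqn{\xi_{12} = f/(1-\sigma_1), \quad \xi_{13} = f/(1-\sigma_2), \quad
#'   \xi_{21} = -f = \xi_{31} = -\xi_{22} = -\xi_{23} = -\xi_{32} =
#'   -\xi_{33},}
#' \eqn{\xi_{11}} carries a composite membrane factor, and
#' \eqn{\xi_{det} = [(\zeta^A)^2 - (\zeta^B)^2]/[(\zeta^A)^2(\zeta^B)^2]}.
#' Signs follow the source formulas; the matrix form [xi_coefficients()] is
#' authoritative where they disagree (the magnitudes match).
#'
#' @param zeta_A,zeta_B Shared polarization coefficients of the two
#'   configurations, each in (0, 1\].
#' @param membrane A [membrane_coefficients()].
#' @param c1bar,c2bar Mean solute concentrations, mol/m^3.
#' @param zero_tolerance Absolute tolerance for the zero/critical class.
#' @return An `xi_summary` object (`source = "simplified"`).
#' @export
xi_simplified <- function(zeta_A, zeta_B, membrane, c1bar, c2bar,
                          zero_tolerance = 1e-3) {
  stopifnot(inherits(membrane, "membrane_coefficients"))
  for (z in c(zeta_A, zeta_B))
    if (!is.finite(z) || z <= 0 || z > 1)
      stop("'zeta' values must lie in (0, 1]", call. = FALSE)
  f <- (zeta_A - zeta_B) / (zeta_A * zeta_B)
  s1 <- membrane$sigma1; s2 <- membrane$sigma2
  w11 <- membrane$omega[1, 1]; w22 <- membrane$omega[2, 2]
  Lp <- membrane$Lp
  xi11 <- f * Lp * (c1bar * w22 * (1 - s1) + c2bar * w11 * (1 - s2)) /
    (w11 * w22 + Lp * (w22 * c1bar * (1 - s1)^2 + w11 * c2bar * (1 - s2)^2))
  xi12 <- f / (1 - s1)
  xi13 <- f / (1 - s2)
  xi <- matrix(c(xi11, xi12, xi13,
                 -f, f, f,
                 -f, f, f),
               3L, 3L, byrow = TRUE,
               dimnames = list(c("v", "1", "2"), c("v", "1", "2")))
  xi_det <- (zeta_A^2 - zeta_B^2) / (zeta_A^2 * zeta_B^2)
  new_xi_summary(xi, xi_det, zero_tolerance, source = "simplified")
}

#' Boundary-layer forms of the configuration-difference factor
#'
#' The factor \eqn{f = (\zeta^A - \zeta^B)/(\zeta^A\zeta^B)} that drives the
#' simplified xi coefficients, re-expressed through the symmetric
#' boundary-layer thicknesses of the two configurations:
#' \deqn{f = \frac{2RT\omega\,(\delta^B - \delta^A)}{D}}
#' and its quadratic counterpart for \eqn{\xi_{det}},
#' \deqn{\frac{(\zeta^A)^2 - (\zeta^B)^2}{(\zeta^A)^2(\zeta^B)^2} =
#'   \frac{4RT\omega}{D^2}\left\{D(\delta^B - \delta^A) +
#'   RT\omega\left[(\delta^B)^2 - (\delta^A)^2\right]\right\}.}
#' The thicknesses are obtained from [delta_from_zeta()], so the returned
#' factors are exactly consistent with direct zeta arithmetic.
#'
#' @param zeta_A,zeta_B Shared polarization coefficients, each in (0, 1\].
#' @param omega Solute permeability, mol/(N s).
#' @param D Diffusion coefficient, m^2/s.
#' @param env A [transport_environment()].
#' @return Named numeric vector `c(linear = , quadratic = )`, both
#'   dimensionless.
#' @export
zeta_difference_factors <- function(zeta_A, zeta_B, omega, D,
                                    env = transport_environment()) {
  dA <- delta_from_zeta(zeta_A, omega, D, env)
  dB <- delta_from_zeta(zeta_B, omega, D, env)
  RT <- env$RT
  c(linear = 2 * RT * omega * (dB - dA) / D,
    quadratic = 4 * RT * omega / D^2 *
      (D * (dB - dA) + RT * omega * (dB^2 - dA^2)))
}

#' Sign-criteria classification of the resistance coefficients
#'
#' For each matrix entry (and the determinant) reports the ordering of the
#' Configuration A, Configuration B and homogeneous values together with the
#' resulting sign of the corresponding xi coefficient — the criteria rows
#' used to read off the direction of natural convection.
#'
#' @param xi An `xi_summary` from [xi_coefficients()].
#' @param R_A,R_B,R_hom The same three [rform_matrix()] objects.
#' @return A data.frame with one row per entry plus a determinant row:
#'   columns `entry`, `R_A`, `R_B`, `R_hom`, `ordering` (`"A>B"`, `"A<B"`,
#'   `"A=B"`), `xi`, `xi_sign` and `interpretation`.
#' @export
classify_signs <- function(xi, R_A, R_B, R_hom) {
  stopifnot(inherits(xi, "xi_summary"))
  tol <- xi$zero_tolerance
  idx <- expand.grid(i = 1:3, j = 1:3)
  idx <- idx[order(idx$i, idx$j), ]
  rows <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx$i[k]; j <- idx$j[k]
    a <- R_A$entries[i, j]; b <- R_B$entries[i, j]
    x <- xi$xi[i, j]
    data.frame(entry = xi_entry_names[(i - 1) * 3 + j],
               R_A = a, R_B = b, R_hom = R_hom$entries[i, j],
               ordering = if (is.na(x) || abs(x) <= tol) "A=B"
                          else if (a > b) "A>B" else "A<B",
               xi = x,
               xi_sign = xi$signs[i, j],
               interpretation = xi$interpretation[i, j])
  })
  det_row <- data.frame(entry = "det",
                        R_A = R_A$det, R_B = R_B$det, R_hom = R_hom$det,
                        ordering = if (is.na(xi$xi_det) ||
                                       abs(xi$xi_det) <= tol) "A=B"
                                   else if (R_A$det > R_B$det) "A>B"
                                   else "A<B",
                        xi = xi$xi_det,
                        xi_sign = xi_sign(xi$xi_det, tol),
                        interpretation = xi_interpret(xi$xi_det, tol))
  out <- rbind(do.call(rbind, rows), det_row)
  rownames(out) <- NULL
  out
}
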