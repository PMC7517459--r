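# Empirical model of the configuration-dependent concentration dependence of
# the polarization coefficient zeta(c1bar). Only plateaus, breakpoints and the
# crossing point are known for the Nephrophan system; the transition between
# plateaus is modelled by a monotone piecewise-cubic (Fritsch-Carlson)
# interpolant through the published anchors, clamped to the plateaus outside
# the transition window. Fully deterministic.

#' Concentration profile of a polarization coefficient
#'
#' Describes how the per-solute polarization coefficient \eqn{\zeta} of one
#' membrane configuration varies with the mean concentration of solute 1:
#' constant plateaus outside a transition window, and a monotone smooth
#' transition through a fixed crossing anchor inside it.
#'
#' @param plateau_low,plateau_high Lower and upper \eqn{\zeta} bounds,
#'   dimensionless, with `plateau_low < crossing_zeta < plateau_high`.
#' @param crossing_concentration Mean solute-1 concentration at which the A
#'   and B profiles of a system intersect, mol/m^3.
#' @param crossing_zeta \eqn{\zeta} value at the crossing, dimensionless.
#' @param transition_start,transition_end Concentration window of the
#'   transition, mol/m^3, bracketing `crossing_concentration`.
#' @param direction `"decreasing"` (Configuration A: starts at the high
#'   plateau) or `"increasing"` (Configuration B: starts at the low plateau).
#' @return An object of class `zeta_profile`.
#' @seealso [nephrophan_zeta_profiles()], [evaluate_profile()]
#' @export
zeta_profile <- function(plateau_low, plateau_high,
                         crossing_concentration, crossing_zeta,
                         transition_start, transition_end,
                         direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  if (!(plateau_low < crossing_zeta && crossing_zeta < plateau_high))
    stop("'crossing_zeta' must lie strictly between the plateaus",
         call. = FALSE)
  if (!(transition_start < crossing_concentration &&
        crossing_concentration < transition_end))
    stop("'crossing_concentration' must lie inside the transition window",
         call. = FALSE)
  if (any(c(plateau_low, plateau_high, crossing_zeta) <= 0) ||
      plateau_high > 1)
    stop("zeta values must lie in (0, 1]", call. = FALSE)
  y_start <- if (direction == "decreasing") plateau_high else plateau_low
  y_end <- if (direction == "decreasing") plateau_low else plateau_high
  x <- c(transition_start, crossing_concentration, transition_end)
  y <- c(y_start, crossing_zeta, y_end)
  structure(
    list(plateau_low = plateau_low, plateau_high = plateau_high,
         crossing_concentration = crossing_concentration,
         crossing_zeta = crossing_zeta,
         transition_start = transition_start,
         transition_end = transition_end,
         direction = direction,
         interpolant = stats::splinefun(x, y, method = "monoH.FC")),
    class = "zeta_profile")
}

#' @export
print.zeta_profile <- function(x, ...) {
  cat(sprintf(
    "zeta profile (%s): %.3g -> %.3g over (%.3g, %.3g] mol/m^3, crossing %.3g @ %.3g\n",
    x$direction,
    if (x$direction == "decreasing") x$plateau_high else x$plateau_low,
    if (x$direction == "decreasing") x$plateau_low else x$plateau_high,
    x$transition_start, x$transition_end,
    x$crossing_zeta, x$crossing_concentration))
  invisible(x)
}

#' Published polarization-coefficient profiles for the Nephrophan system
#'
#' The reported concentration dependence of the per-solute polarization
#' coefficients for glucose in aqueous ethanol on a Nephrophan membrane:
#' Configuration A holds \eqn{\zeta = 0.5} up to 4 mol/m^3, decreases
#' monotonically across (4, 12.72\] and stays at 0.03 above; Configuration B
#' mirrors it (0.03 below 5.41 mol/m^3, rising to 0.5 above 12.72). Both pass
#' through \eqn{\zeta = 0.234} at 9.24 mol/m^3, the concentration at which
#' chamber densities match. Solutes 1 and 2 share the same profile.
#'
#' @return A list with `zeta_profile` elements `A` and `B`.
#' @export
#' @examples
#' pr <- nephrophan_zeta_profiles()
#' evaluate_profile(pr$A, c(2, 9.24, 20))
nephrophan_zeta_profiles <- function() {
  list(
    A = zeta_profile(plateau_low = 0.03, plateau_high = 0.5,
                     crossing_concentration = 9.24, crossing_zeta = 0.234,
                     transition_start = 4, transition_end = 12.72,
                     direction = "decreasing"),
    B = zeta_profile(plateau_low = 0.03, plateau_high = 0.5,
                     crossing_concentration = 9.24, crossing_zeta = 0.234,
                     transition_start = 5.41, transition_end = 12.72,
                     direction = "increasing")
  )
}

#' Evaluate a polarization-coefficient profile
#'
#' Continuous, monotone evaluation of a [zeta_profile()], clamped to the
#' plateau values outside the transition window.
#'
#' @param profile A `zeta_profile` object.
#' @param c1bar Mean solute-1 concentration(s), mol/m^3, positive. Vectorised.
#' @return \eqn{\zeta} value(s) within `[plateau_low, plateau_high]`.
#' @export
evaluate_profile <- function(profile, c1bar) {
  stopifnot(inherits(profile, "zeta_profile"))
  if (any(!is.finite(c1bar)) || any(c1bar <= 0))
    stop("'c1bar' must be positive", call. = FALSE)
  x <- pmin(pmax(c1bar, profile$transition_start), profile$transition_end)
  y <- profile$interpolant(x)
  pmin(pmax(y, profile$plateau_low), profile$plateau_high)
}
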