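# Kedem-Caplan-Peusner coupling statistics derived from the resistance
# matrix: degrees of coupling r_ij, energy-conversion efficiencies e_ij, the
# "super Q_R" coupling parameter, and sweep-level summaries with A/B
# crossing detection.

coupling_pairs <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L),
                        c(3L, 1L), c(2L, 3L), c(3L, 2L))

#' Degree of coupling between two flux-force processes
#'
#' The Kedem--Caplan--Peusner degree of coupling
#' \deqn{r_{ij} = \frac{-R_{ij}}{\sqrt{R_{ii} R_{jj}}}.}
#' In `"reduced"` mode (default) the computation uses dimensionless entries:
#' an `as_printed` matrix has its (2,1) entry divided by \eqn{\bar{C}_1} and
#' its (3,1) entry by \eqn{\bar{C}_2} first (a `strict_inverse` matrix
#' already is in this form), so that every \eqn{r_{ij}} is dimensionless and
#' bounded by 1 for passive transport. `"literal"` mode applies the formula
#' to the stored entries unchanged; on an as-printed matrix the (2,1)/(3,1)
#' results then carry concentration units and can exceed 1, so this mode is
#' only useful for auditing.
#'
#' @param matrix An [rform_matrix()].
#' @param i,j Indices in 1..3 (1 = volume flow, 2 = solute 1, 3 = solute 2).
#' @param reduction `"reduced"` (default) or `"literal"`.
#' @return The degree of coupling, dimensionless in reduced mode.
#' @export
degree_of_coupling <- function(matrix, i, j,
                               reduction = c("reduced", "literal")) {
  stopifnot(inherits(matrix, "rform_matrix"))
  reduction <- match.arg(reduction)
  E <- matrix$entries
  if (reduction == "reduced" && matrix$variant == "as_printed") {
    E[2, 1] <- E[2, 1] / matrix$c1bar
    E[3, 1] <- E[3, 1] / matrix$c2bar
  }
  if (E[i, i] <= 0 || E[j, j] <= 0)
    stop("diagonal resistance entries must be positive", call. = FALSE)
  -E[i, j] / sqrt(E[i, i] * E[j, j])
}

#' Energy-conversion efficiency from a pair of coupling degrees
#'
#' \deqn{e_{ij} = \frac{r_{ji}^2}{\left(1 + \sqrt{1 - r_{ij} r_{ji}}\right)^2}.}
#' When \eqn{r_{ij} = r_{ji} = r} this equals the maximum energy-conversion
#' efficiency [e_max()].
#'
#' @param r_ij,r_ji Degrees of coupling with `r_ij * r_ji <= 1`.
#' @return Efficiency in \[0, 1\].
#' @export
energy_conversion <- function(r_ij, r_ji) {
  p <- r_ij * r_ji
  if (any(p > 1)) stop("'r_ij * r_ji' must not exceed 1", call. = FALSE)
  r_ji^2 / (1 + sqrt(1 - p))^2
}

#' Maximum energy-conversion efficiency
#'
#' The Kedem--Caplan bound \eqn{e_{max} = r^2 [1 + (1 - r^2)^{1/2}]^{-2}}
#' for a symmetric degree of coupling r.
#'
#' @param r Degree of coupling, `|r| <= 1`. Vectorised.
#' @return Efficiency in \[0, 1\].
#' @export
e_max <- function(r) {
  if (any(abs(r) > 1)) stop("'|r|' must not exceed 1", call. = FALSE)
  r^2 / (1 + sqrt(1 - r^2))^2
}

#' Q_R coupling parameter
#'
#' Peusner's "super Q_R" parameter,
#' \deqn{Q_R = \frac{r_{ij} r_{ji}}{2 - r_{ij} r_{ji}},}
#' monotone increasing in the product and equal to 1 at complete coupling
#' (\eqn{r_{ij} r_{ji} = 1}).
#'
#' @param r_ij,r_ji Degrees of coupling with `r_ij * r_ji < 2`.
#' @return The coupling parameter (in \[0, 1\] for physical couplings).
#' @export
qr_parameter <- function(r_ij, r_ji) {
  p <- r_ij * r_ji
  if (any(p >= 2)) stop("'r_ij * r_ji' must be below 2", call. = FALSE)
  p / (2 - p)
}

#' All coupling statistics of one resistance matrix
#'
#' Degrees of coupling for the six ordered index pairs, energy-conversion
#' efficiencies, and the Q_R parameter per unordered pair.
#'
#' @param matrix An [rform_matrix()].
#' @param reduction Passed to [degree_of_coupling()].
#' @return An object of class `coupling_summary`: list with named vectors
#'   `r` (r12, r21, r13, r31, r23, r32), `e` (same pairs) and `q` (q12, q13,
#'   q23), plus `reduction` and `configuration`.
#' @export
coupling_summary <- function(matrix, reduction = c("reduced", "literal")) {
  reduction <- match.arg(reduction)
  r <- apply(coupling_pairs, 1L, function(p)
    degree_of_coupling(matrix, p[1L], p[2L], reduction))
  names(r) <- apply(coupling_pairs, 1L, function(p)
    paste0("r", p[1L], p[2L]))
  e <- c(e12 = energy_conversion(r["r12"], r["r21"]),
         e21 = energy_conversion(r["r21"], r["r12"]),
         e13 = energy_conversion(r["r13"], r["r31"]),
         e31 = energy_conversion(r["r31"], r["r13"]),
         e23 = energy_conversion(r["r23"], r["r32"]),
         e32 = energy_conversion(r["r32"], r["r23"]))
  names(e) <- c("e12", "e21", "e13", "e31", "e23", "e32")
  q <- c(q12 = qr_parameter(r[["r12"]], r[["r21"]]),
         q13 = qr_parameter(r[["r13"]], r[["r31"]]),
         q23 = qr_parameter(r[["r23"]], r[["r32"]]))
  structure(list(r = r, e = e, q = q, reduction = reduction,
                 configuration = matrix$configuration),
            class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("Coupling summary (%s, %s)\n", x$configuration, x$reduction))
  cat("  r:", paste(sprintf("%s=%.4g", names(x$r), x$r), collapse = " "), "\n")
  cat("  e:", paste(sprintf("%s=%.4g", names(x$e), x$e), collapse = " "), "\n")
  cat("  Q_R:", paste(sprintf("%s=%.4g", names(x$q), x$q), collapse = " "),
      "\n")
  invisible(x)
}

find_crossing <- function(x, dy, tol = 1e-3) {
  # root of the cubic-interpolated A-B difference; NA when the grid does not
  # bracket a sign change
  ok <- is.finite(dy)
  x <- x[ok]; dy <- dy[ok]
  if (length(x) < 2L || min(dy) > 0 || max(dy) < 0) return(NA_real_)
  f <- stats::splinefun(x, dy, method = "natural")
  idx <- which(dy[-1L] * dy[-length(dy)] <= 0)[1L]
  if (is.na(idx)) return(NA_real_)
  if (dy[idx] == 0) return(x[idx])
  stats::uniroot(f, lower = x[idx], upper = x[idx + 1L], tol = tol)$root
}

#' Summary of coupling coefficients over a concentration sweep
#'
#' Reports, for each coupling column pair in a sweep table, the range of the
#' A and B series and the concentration at which they cross (bisection on
#' the interpolated A-B difference; `NA` when the grid does not bracket a
#' sign change).
#'
#' @param sweep A data.frame from [run_sweep()].
#' @param quantities Base column names to summarise (e.g. `"r12"`); columns
#'   `<name>_A` and `<name>_B` must exist.
#' @param x_column Column holding the concentration grid.
#' @param crossing_tolerance Tolerance passed to the root finder, mol/m^3.
#' @return A data.frame with columns `quantity`, `min_A`, `max_A`, `min_B`,
#'   `max_B`, `crossing`.
#' @export
coupling_sweep_summary <- function(sweep,
                                   quantities = c("r12", "r21", "r13",
                                                  "r31", "QR12", "QR13"),
                                   x_column = "c1bar",
                                   crossing_tolerance = 1e-3) {
  stopifnot(is.data.frame(sweep), x_column %in% names(sweep))
  x <- sweep[[x_column]]
  rows <- lapply(quantities, function(q) {
    a <- sweep[[paste0(q, "_A")]]
    b <- sweep[[paste0(q, "_B")]]
    if (is.null(a) || is.null(b))
      stop("sweep lacks columns for quantity ", q, call. = FALSE)
    data.frame(quantity = q,
               min_A = min(a, na.rm = TRUE), max_A = max(a, na.rm = TRUE),
               min_B = min(b, na.rm = TRUE), max_B = max(b, na.rm = TRUE),
               crossing = find_crossing(x, a - b, crossing_tolerance))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
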