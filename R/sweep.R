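# Concentration sweeps: evaluate the whole coefficient set (boundary layers,
# fluxes, resistance matrices for A/B/homogeneous, xi diagnostics, coupling
# statistics, convective regime) over a grid of glucose bath concentrations.

#' Specification of a concentration sweep
#'
#' @param c1h_grid Strictly increasing grid of solute-1 chamber-h
#'   concentrations, mol/m^3. The mean concentration column is derived via
#'   the log-mean with `C1l`.
#' @param C2h,C1l,C2l Fixed bath concentrations, mol/m^3.
#' @param dP Hydrostatic pressure difference, Pa.
#' @param cp_source `"profiles"` (per-configuration zeta from
#'   concentration profiles), `"homogeneous"` (all zeta = 1 for A and B
#'   alike) or `"explicit"` (fixed `zeta_A`, `zeta_B`).
#' @param variant Resistance-matrix variant, `"strict_inverse"` or
#'   `"as_printed"`; coupling statistics always use the reduced
#'   (dimensionless) form.
#' @param zeta_A,zeta_B Length-2 vectors `c(zeta1, zeta2)` used when
#'   `cp_source = "explicit"`.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(c1h_grid = seq(1, 101, by = 2),
                       C2h = 201, C1l = 1, C2l = 1, dP = 0,
                       cp_source = c("profiles", "homogeneous", "explicit"),
                       variant = c("strict_inverse", "as_printed"),
                       zeta_A = NULL, zeta_B = NULL) {
  cp_source <- match.arg(cp_source)
  variant <- match.arg(variant)
  if (length(c1h_grid) < 1L || any(diff(c1h_grid) <= 0))
    stop("'c1h_grid' must be strictly increasing", call. = FALSE)
  if (cp_source == "explicit" && (is.null(zeta_A) || is.null(zeta_B)))
    stop("explicit cp_source requires 'zeta_A' and 'zeta_B'", call. = FALSE)
  structure(list(c1h_grid = c1h_grid, C2h = C2h, C1l = C1l, C2l = C2l,
                 dP = dP, cp_source = cp_source, variant = variant,
                 zeta_A = zeta_A, zeta_B = zeta_B),
            class = "sweep_spec")
}

variant_suffix <- function(variant) {
  if (variant == "strict_inverse") "strict" else "printed"
}

sweep_row <- function(spec, membrane, env, profiles, C1h) {
  baths <- bath_state(C1h, spec$C1l, spec$C2h, spec$C2l, dP = spec$dP)
  c1 <- baths$c1bar; c2 <- baths$c2bar
  z <- switch(spec$cp_source,
    profiles = list(A = rep(evaluate_profile(profiles$A, c1), 2L),
                    B = rep(evaluate_profile(profiles$B, c1), 2L)),
    homogeneous = list(A = c(1, 1), B = c(1, 1)),
    explicit = list(A = spec$zeta_A, B = spec$zeta_B))
  cp_A <- cp_reduced(z$A[1L], z$A[2L], "A")
  cp_B <- cp_reduced(z$B[1L], z$B[2L], "B")
  cp_h <- cp_homogeneous()

  out <- c(C1h = C1h, c1bar = c1, c2bar = c2,
           zeta1_A = z$A[1L], zeta2_A = z$A[2L],
           zeta1_B = z$B[1L], zeta2_B = z$B[2L])

  # boundary layers and convection (solute-1 layer, D11)
  D11 <- env$D[1L, 1L]
  delta_A <- if (is.finite(D11))
    delta_from_zeta(z$A[1L], membrane$omega[1, 1], D11, env) else NA_real_
  delta_B <- if (is.finite(D11))
    delta_from_zeta(z$B[1L], membrane$omega[1, 1], D11, env) else NA_real_
  drho <- tryCatch(density_difference(C1h - spec$C1l, spec$C2h - spec$C2l,
                                      env),
                   error = function(e) NA_real_)
  ra_A <- if (is.finite(drho) && is.finite(delta_A))
    tryCatch(rayleigh_number(drho, delta_A, env), error = function(e) NA_real_)
    else NA_real_
  ra_B <- if (is.finite(drho) && is.finite(delta_B))
    tryCatch(rayleigh_number(drho, delta_B, env), error = function(e) NA_real_)
    else NA_real_
  out <- c(out, delta_A = delta_A, delta_B = delta_B, delta_rho = drho,
           rayleigh_A = ra_A, rayleigh_B = ra_B)
  regime_A <- if (is.finite(drho))
    classify_convection("A", drho, ra_A)$regime else NA_character_
  regime_B <- if (is.finite(drho))
    classify_convection("B", drho, ra_B)$regime else NA_character_

  # fluxes
  fl <- lapply(list(A = cp_A, B = cp_B, hom = cp_h), function(cp)
    kk_fluxes(membrane, cp, baths, env))
  for (nm in names(fl))
    out <- c(out, stats::setNames(
      c(fl[[nm]]$Jv, fl[[nm]]$J1, fl[[nm]]$J2),
      paste0(c("Jv_", "J1_", "J2_"), nm)))

  # resistance matrices
  sfx <- variant_suffix(spec$variant)
  Rm <- lapply(list(A = cp_A, B = cp_B, hom = cp_h), function(cp)
    rform_matrix(membrane, cp, c1, c2, variant = spec$variant))
  labels <- c("11", "12", "13", "21", "22", "23", "31", "32", "33")
  for (nm in names(Rm)) {
    vals <- as.vector(t(Rm[[nm]]$entries))
    out <- c(out, stats::setNames(vals, paste0("R", labels, "_", nm, "_", sfx)),
             stats::setNames(Rm[[nm]]$det, paste0("Rdet_", nm, "_", sfx)))
  }

  # xi diagnostics
  xs <- xi_coefficients(Rm$A, Rm$B, Rm$hom)
  out <- c(out, stats::setNames(as.vector(t(xs$xi)), paste0("xi_", labels)),
           xi_det = xs$xi_det)

  # coupling statistics (always reduced/dimensionless)
  for (nm in names(Rm)) {
    cs <- coupling_summary(Rm[[nm]], reduction = "reduced")
    out <- c(out,
             stats::setNames(cs$r, paste0(names(cs$r), "_", nm)),
             stats::setNames(cs$e, paste0(names(cs$e), "_", nm)),
             stats::setNames(cs$q, paste0(c("QR12", "QR13", "QR23"), "_", nm)))
  }
  list(numeric = out, regime_A = regime_A, regime_B = regime_B,
       error = NA_character_)
}

#' Run a concentration sweep
#'
#' Evaluates every coefficient group on the grid of a [sweep_spec()]: mean
#' concentrations, per-configuration polarization coefficients and boundary
#' layers, density difference and Rayleigh numbers with regime labels,
#' fluxes, resistance coefficients and determinants for Configurations A, B
#' and the homogeneous case (columns suffixed with the variant, e.g.
#' `R12_A_strict`), xi diagnostics, and reduced coupling/energy/Q_R
#' statistics. Fully deterministic.
#'
#' A failure at one grid point does not abort the sweep: the offending row
#' is filled with `NA` and its message recorded in the `error` column; the
#' number of failed rows is available as `attr(x, "n_errors")`.
#'
#' @param spec A [sweep_spec()].
#' @param membrane A [membrane_coefficients()].
#' @param env A [transport_environment()].
#' @param profiles Profiles list as from [nephrophan_zeta_profiles()]; used
#'   when `spec$cp_source == "profiles"`.
#' @return A data.frame, one row per grid point.
#' @export
run_sweep <- function(spec, membrane, env,
                      profiles = nephrophan_zeta_profiles()) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(spec$c1h_grid, function(C1h) {
    tryCatch(sweep_row(spec, membrane, env, profiles, C1h),
             error = function(e) list(numeric = c(C1h = C1h),
                                      regime_A = NA_character_,
                                      regime_B = NA_character_,
                                      error = conditionMessage(e)))
  })
  ok <- which(!vapply(rows, function(r) is.na(r$numeric["c1bar"]) &&
                        length(r$numeric) == 1L, logical(1L)))
  if (length(ok) == 0L) stop("every sweep row failed", call. = FALSE)
  template <- names(rows[[ok[1L]]]$numeric)
  num <- do.call(rbind, lapply(rows, function(r) {
    v <- stats::setNames(rep(NA_real_, length(template)), template)
    v[intersect(names(r$numeric), template)] <-
      r$numeric[intersect(names(r$numeric), template)]
    v
  }))
  out <- as.data.frame(num)
  out$regime_A <- vapply(rows, `[[`, character(1L), "regime_A")
  out$regime_B <- vapply(rows, `[[`, character(1L), "regime_B")
  out$error <- vapply(rows, `[[`, character(1L), "error")
  attr(out, "variant") <- spec$variant
  attr(out, "n_errors") <- sum(!is.na(out$error))
  out
}

#' Write a sweep table as CSV
#'
#' Comma-separated, '.' decimal, scientific notation with 10 significant
#' digits, preceded by a comment line stating that all values are in SI
#' units. Output is byte-identical across repeated runs on the same input.
#'
#' @param sweep Data.frame from [run_sweep()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(is.data.frame(sweep))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("# kkpeusner sweep; SI units throughout",
                   "(mol/m^3, Pa, m, s, N); zeta, xi, r, e, Q_R",
                   "dimensionless"), con)
  fmt <- vapply(sweep, function(col) {
    if (is.numeric(col)) formatC(col, digits = 10, format = "e")
    else as.character(col)
  }, character(nrow(sweep)))
  if (nrow(sweep) == 1L) fmt <- matrix(fmt, nrow = 1L,
                                       dimnames = list(NULL, names(sweep)))
  writeLines(paste(colnames(fmt), collapse = ","), con)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}
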