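---
title: "The resistance-matrix form of the Kedem–Katchalsky equations under concentration polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The resistance-matrix form of the Kedem–Katchalsky equations under concentration polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kkpeusner)
```

## The transport model

The package describes passive, isothermal, quasi-stationary transport of a
ternary non-electrolyte solution (solvent plus two solutes) across a
selective, electroneutral membrane mounted horizontally. The membrane is a
black box characterised by practical coefficients: hydraulic permeability
$L_p$ (m$^3$/(N s)), reflection coefficients $\sigma_1, \sigma_2$, and the
solute permeability matrix $\omega_{kf}$ (mol/(N s)) whose off-diagonal
entries describe cross-diffusion. The driving forces are the hydrostatic
pressure difference $\Delta P$ and the van 't Hoff osmotic pressure
differences $\Delta\pi_k = RT(C_{kh} - C_{kl})$; the mean intramembrane
concentration is the log-mean $\bar C_k = (C_{kh}-C_{kl})/\ln(C_{kh}/C_{kl})$.

Unstirred solutions develop concentration boundary layers (CBLs) on both
membrane faces. Their effect is modelled multiplicatively: each practical
coefficient is attenuated by a polarization coefficient $\zeta \in (0,1]$
(hydraulic $\zeta_p$, osmotic $\zeta_{vk}$, advective $\zeta_{ak}$,
diffusive $\zeta_{skf}$), giving the polarized flux equations implemented in
`kk_fluxes()`. Setting every $\zeta = 1$ recovers the classical equations
for vigorously stirred ("homogeneous") solutions. For the reference system
(Nephrophan membrane, glucose "1" in aqueous ethanol "2") the empirically
supported reduction `cp_reduced()` applies: $\zeta_p = \zeta_{a1} =
\zeta_{a2} = 1$ and one shared coefficient per solute.

## The resistance form and its two variants

Rewriting the flux equations so that the forces
$(\Delta P - \Delta\pi_1 - \Delta\pi_2,\ \Delta\pi_1/\bar C_1,\
\Delta\pi_2/\bar C_2)$ appear as a matrix times the fluxes $(J_v, J_1, J_2)$
yields the resistance matrix built by `rform_matrix()`. Its entries have
closed forms in the practical coefficients, the $\zeta$s and the mean
concentrations, with the common denominator
$\gamma_\zeta = \zeta_{s11}\omega_{11}\zeta_{s22}\omega_{22} -
\zeta_{s12}\omega_{12}\zeta_{s21}\omega_{21}$ (a typed singularity error is
raised when $|\gamma_\zeta| < 10^{-30}$ in SI units).

Two variants are first-class, because the source formulas and the exact
inversion disagree in two entries:

- **`strict_inverse`** (default): the exact inverse of the conductance map
  implied by the flux equations. `invert_conductance_oracle()` rebuilds that
  inverse numerically, column by column at unit forces, and the test suite
  verifies agreement to 10 significant digits across random parameter sets.
  Every row is dimensionally consistent, the determinant has the closed form
  $\det R = [\zeta_p L_p \bar C_1 \bar C_2 \gamma_\zeta]^{-1}$ (positive iff
  $\gamma_\zeta > 0$), and all coupling statistics built from it are
  dimensionless.
- **`as_printed`**: the literal source coefficient formulas, which carry an
  extra factor $\bar C_1$ in the (2,1) entry and $\bar C_2$ in the (3,1)
  entry relative to the strict inverse. This variant reproduces the
  published coefficient magnitudes and unit statements and is kept for
  auditability. (One typographical repair is applied in both variants: the
  published (3,1) formula omits the factor $\omega_{21}$ that dimensional
  analysis and symmetry with the (2,1) entry require.)

Two further readings were fixed the same way: the determinant typography is
ambiguous between a product and a reciprocal, and the reciprocal reading is
adopted because it equals the brute-force determinant of the strict matrix
and honours the stated sign rule; and the advective term of $J_2$ uses
$\bar C_2$ (the form consistent with the matrix coefficients and with exact
inversion), with an `advective = "as_printed"` toggle in `kk_fluxes()` that
restores the literal $\bar C_1$.

## Boundary layers, density and convection

`zeta_from_delta()` and `delta_from_zeta()` convert between $\zeta$ and the
CBL thickness $\delta$ through $\zeta = D/(D + 2RT\omega\delta)$ (the
symmetric-layer form; the general two-layer form is also implemented). The
chamber density difference is linearised with the partials
$\partial\rho/\partial C_k$, and the concentration Rayleigh number
$R_C = g\,\Delta\rho\,\delta^3/(\rho\nu D_{11})$ measures buoyant
(in)stability of the CBL complex. `classify_convection()` keys the regime on
$\Delta\rho$ relative to a configurable critical value (default 0.046
kg/m$^3$, tolerance $10^{-3}$ kg/m$^3$), because the density difference is
the physically causal quantity; $R_C$ against its rigid–free critical value
1100.6 is reported as a secondary indicator. Configuration A (dilute
solution above the membrane) is unstable below the critical density
difference and stable above it; Configuration B is the mirror image.

## The modelled zeta profiles

The concentration dependence of the per-solute polarization coefficient is
known for the reference system only through plateaus, breakpoints and one
crossing: Configuration A holds $\zeta = 0.5$ up to 4 mol/m$^3$, falls to
0.03 by 12.72 mol/m$^3$; Configuration B mirrors it starting at 5.41
mol/m$^3$; both pass through $\zeta = 0.234$ at $\bar C_1 = 9.24$
mol/m$^3$, where the chamber densities match. The transition shape between
those anchors is not published. `zeta_profile()` therefore interpolates the
three anchors with a monotone piecewise-cubic (Fritsch–Carlson) spline,
clamped to the plateaus outside the window — smooth, monotone, and exactly
honouring every published anchor. Both solutes share one profile by default
(the published plateaus coincide), separate profiles are supported, and the
profiles are deterministic: no randomness enters anywhere in the package.

What passing the profile-driven tests shows — and does not show — about real
data: the profiles emulate the *reported shape* of the measured curves, so
sweep-level statements (all A/B coefficient, $\xi$ and coupling curves
crossing at 9.24 mol/m$^3$; the sign pattern of $\xi$ on each side) test the
formalism, not the laboratory system. Point values of polarized
coefficients between the plateaus depend on the unpublished experimental
curves and are not reproducible from this model; only homogeneous-solution
values and structural identities are pinned to published numbers.

## Configuration diagnostics and their simplified forms

`xi_coefficients()` computes $\xi_{ij} = (R^A_{ij} - R^B_{ij})/R_{ij}$ and
$\xi_{det}$ from actual matrices — this is the authoritative definition.
Negative $\xi$ marks upward-directed free convection, positive downward,
zero (within a configurable tolerance, default $10^{-3}$) the critical
state; a zero homogeneous denominator flags the entry as undefined rather
than erroring. The simplified closed forms in `xi_simplified()` (valid for
the reduced model with negligible cross-permeabilities) are carried with the
signs of their source formulas. Those printed signs conflict with the
matrix definition for several entries — direct computation gives, e.g.,
$\xi_{22} = -(\zeta^A-\zeta^B)/(\zeta^A\zeta^B)$ where the printed chain
asserts the opposite sign, and the printed criteria table agrees with the
matrix form. The package does not silently "fix" the simplified forms: the
magnitudes agree to within 5% (tested), the matrix form decides the sign,
and `classify_signs()` tabulates the orderings.

## Coupling statistics and what the second law actually bounds

From the (reduced, dimensionless) matrix, `degree_of_coupling()` computes
$r_{ij} = -R_{ij}/\sqrt{R_{ii}R_{jj}}$ (the minus sign is applied uniformly;
off-diagonal resistances are negative here, so the $r$ values come out
positive), `energy_conversion()` computes
$e_{ij} = r_{ji}^2\,[1+\sqrt{1-r_{ij}r_{ji}}]^{-2}$ and `qr_parameter()`
computes $Q_R = r_{ij}r_{ji}/(2 - r_{ij}r_{ji})$. A "literal" mode applies
the formula to an as-printed matrix unchanged; its (2,1)/(3,1) results are
then dimensional and can exceed 1, which is why the reduced form is the
default.

A subtlety worth stating precisely: for this polarized model the matrix is
non-reciprocal ($R_{ij} \neq R_{ji}$), and the second law — positive
dissipation, i.e. a positive-semidefinite symmetric part of the conductance
map — bounds only the *product*: $R_{ij}R_{ji} \le \left(\tfrac{R_{ij} +
R_{ji}}{2}\right)^2 \le R_{ii}R_{jj}$, hence $r_{ij}r_{ji} \le 1$ and with
it $0 \le e \le 1$ and $Q_R \le 1$ ($Q_R \ge 0$ whenever the pair couples
with a non-negative product). The individual bound $|r_{ij}| \le 1$ is a
theorem only for reciprocal matrices; under strong polarization asymmetry a
single $r_{ij}$ can exceed 1 without violating the second law. The property
tests therefore draw random parameter sets, reject those violating
passivity, and assert exactly the product-based bounds; the individual
$0 \le r \le 1$ statement is asserted over the full reference-system sweep,
where it holds.

## Numerical choices and defaults

- Units are strict SI throughout (mol/m$^3$, Pa, m, s); display scaling is
  left to formatting.
- Gas constant default 8.314 J/(mol K); temperature is not part of the
  published data set and defaults to 298.15 K, configurable in
  `transport_environment()`. All pinned quantities are either
  temperature-independent or use published inputs directly.
- Log-mean at $C_h = C_l$ returns the continuous limit $C$ rather than
  erroring.
- Crossing detection in sweeps interpolates the A$-$B difference with a
  cubic spline and bisects (tolerance $10^{-3}$ mol/m$^3$).
- Sweeps are specified by the chamber concentration $C_{1h}$ (default grid
  1 to 101 mol/m$^3$ in steps of 2, covering the studied range) with the
  mean concentration derived; errors at single grid points are recorded in
  the row and do not abort the sweep. CSV output uses 10 significant
  digits and is byte-identical across runs.
- Configuration files are YAML with flat documented keys
  (`membrane.Lp`, ..., `baths.dP`); round-tripping is lossless.
- Only the solute-1 diffusion coefficient $D_{11}$ is part of the reference
  data set; the remaining diffusion entries are left unset and operations
  needing them require explicit values.
- Test problem sizes (grids of ~70–140 points, 20–30 random draws per
  property) were chosen as the smallest sizes that exercise both sides of
  every crossing and the full parameter ranges.

## Known limitations

- Point values of the polarized coefficients between the plateau regions
  depend on the unpublished experimental $\zeta$ curves (see above); a few
  published figure-level values (the homogeneous determinant endpoint, one
  diagonal entry at the lowest concentration, the $\xi$ extrema, and the
  published efficiency and $r_{13}$ ranges) are not recoverable from the
  published formulas and parameters under any variant, and are deliberately
  not asserted.
- The published $\zeta$–$\delta$ pairs from the two boundary-layer figures
  are mutually inconsistent with the conversion formula at any plausible
  temperature; the package implements the formula and treats those figures
  as independent empirical inputs.
- No transient CBL growth, no hydrodynamic simulation of convection onset,
  no electrolyte extensions, and no fitting of practical coefficients from
  raw flux measurements.
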