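# kkpeusner

Network-thermodynamic analysis of passive membrane transport for ternary
non-electrolyte solutions: the resistance-matrix (Peusner *R*-form) version of
the Kedem–Katchalsky equations, with and without concentration polarization.

## The problem

A horizontal, selective membrane separating two solutions of two
non-electrolytes (the reference system: a Nephrophan cellulose-acetate
membrane with glucose in aqueous ethanol) transports volume and solutes
according to the Kedem–Katchalsky (K–K) equations. The membrane is a "black
box" described by practical coefficients: hydraulic permeability L<sub>p</sub>,
reflection coefficients σ₁, σ₂ and a 2×2 solute permeability matrix
ω<sub>kf</sub>. When the solutions are not stirred, concentration boundary
layers (CBLs) form on both faces and attenuate every driving force; the
attenuation is captured by polarization coefficients ζ ∈ (0, 1]. Because the
membrane is horizontal, gravity makes the CBL complex orientation-dependent:
with the dilute solution on top (Configuration A) the layers can become
buoyantly unstable and free convection destroys them, while the reversed
orientation (Configuration B) is stable — and the roles swap once the chamber
density difference crosses zero.

## The model

The package rewrites the polarized K–K flux equations

```
Jv = ζp Lp (ΔP − ζv1 σ1 Δπ1 − ζv2 σ2 Δπ2)
J1 = ζs11 ω11 Δπ1 + ζs12 ω12 Δπ2 + C̄1 (1 − ζa1 σ1) Jv
J2 = ζs21 ω21 Δπ1 + ζs22 ω22 Δπ2 + C̄2 (1 − ζa2 σ2) Jv
```

in resistance form: the forces (ΔP − Δπ₁ − Δπ₂, Δπ₁/C̄₁, Δπ₂/C̄₂) are a 3×3
matrix **R** times the fluxes (J_v, J₁, J₂), where C̄ₖ is the log-mean
concentration and Δπₖ = RT(C<sub>kh</sub> − C<sub>kl</sub>). Everything else
derives from **R**:

- **det R** = [ζp Lp C̄₁ C̄₂ γ_ζ]⁻¹ with γ_ζ the ζ-weighted permeability
  determinant;
- configuration diagnostics ξᵢⱼ = (Rᵢⱼᴬ − Rᵢⱼᴮ)/Rᵢⱼ, whose signs read off the
  direction of free convection (ξ < 0 upwards, ξ > 0 downwards, ξ = 0
  critical);
- degrees of coupling rᵢⱼ = −Rᵢⱼ/√(Rᵢᵢ Rⱼⱼ), energy-conversion efficiencies
  eᵢⱼ = rⱼᵢ² [1 + √(1 − rᵢⱼ rⱼᵢ)]⁻², and Peusner's coupling parameter
  Q_R = rᵢⱼ rⱼᵢ/(2 − rᵢⱼ rⱼᵢ);
- CBL thicknesses via ζ = D/(D + 2RTωδ), solution density differences, and
  the concentration Rayleigh number R_C = g Δρ δ³/(ρ ν D₁₁) governing
  convection onset.

Two matrix variants are carried side by side: `strict_inverse` (the exact,
dimensionally consistent inverse of the conductance map — the default for
determinants and coupling statistics) and `as_printed` (the source
coefficient formulas, which leave an extra concentration factor in the
(2,1)/(3,1) entries). See the methods vignette
(`vignettes/rform-methods.Rmd`) for why both exist.

## Worked example

```r
library(kkpeusner)

fx <- nephrophan_fixture()        # published Nephrophan/glucose/ethanol set
fx$baths
#> Bath state
#>   solute 1: Ch = 33.44, Cl = 1  (log-mean 9.243) mol/m^3
#>   solute 2: Ch = 201, Cl = 1  (log-mean 37.71) mol/m^3
#>   dP = 0 Pa

R <- rform_matrix(fx$membrane, cp_homogeneous(),
                  c1bar = fx$baths$c1bar, c2bar = fx$baths$c2bar)
R
#> Resistance matrix (homogeneous, strict_inverse), det = 5.11788e+26 m^3 N^3 s^3/mol^4
#>              v            1            2
#> v 239173000000 -1.16361e+09 -6.81752e+08
#> 1  -1164720000  1.35240e+08 -7.66046e+03
#> 2   -681493000 -3.77814e+04  1.85430e+07

coupling_summary(R)
#> Coupling summary (homogeneous, reduced)
#>   r: r12=0.2046 r21=0.2048 r13=0.3237 r31=0.3236 r23=0.000153 r32=0.0007545
#>   e: e12=0.01071 e21=0.01069 e13=0.02765 e31=0.02767 e23=1.423e-07 e32=5.85e-09
#>   Q_R: q12=0.0214 q13=0.05528 q23=5.771e-08

drho <- density_difference(33.44 - 1, 201 - 1, fx$environment)  # 0.0464 kg/m^3
classify_convection("A", drho, rayleigh_number(drho, 1.3e-3, fx$environment))
#> Configuration A: critical (delta_rho = 0.0464 kg/m^3, R_C = 1366 vs crit 1101)
```

Reading: at the glucose bath concentration 33.44 mol/m³ the mean
concentration is 9.24 mol/m³ — the point where the two chambers have equal
density. The volume flow is weakly coupled to both solute flows (r₁₂ ≈ 0.20,
r₁₃ ≈ 0.32 here), the solute–solute coupling is negligible, at most a few per
cent of the dissipation is convertible between processes, and the CBL complex
sits at its critical (orientation-independent) state.

Concentration sweeps over the studied glucose range, with the
configuration-dependent ζ profiles, come from `run_sweep()`:

```r
sw <- run_sweep(sweep_spec(), fx$membrane, fx$environment)
coupling_sweep_summary(sw)    # ranges and the A/B crossing near 9.24 mol/m^3
```

A small CLI wraps the same functions
(`Rscript inst/cli/kkp.R fixture --out cfg.yml`, then `compute`, `sweep`,
`classify`).

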