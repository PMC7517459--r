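env0 <- transport_environment(temperature = 298.15)

test_that("xi vanishes for identical configurations and is antisymmetric under swap", {
  m <- profile_matrices(3)
  xs0 <- xi_coefficients(m$A, m$A, m$hom)
  expect_true(all(xs0$xi == 0))
  expect_identical(xs0$xi_det, 0)
  xab <- xi_coefficients(m$A, m$B, m$hom)
  xba <- xi_coefficients(m$B, m$A, m$hom)
  expect_equal(xab$xi, -xba$xi)
  expect_equal(xab$xi_det, -xba$xi_det)
})

test_that("every xi entry is zero at the density-matching concentration", {
  m <- profile_matrices(9.24)
  xs <- xi_coefficients(m$A, m$B, m$hom)
  expect_true(all(abs(xs$xi) < 1e-3))
  expect_lt(abs(xs$xi_det), 1e-3)
  expect_true(all(xs$interpretation == "critical"))
})

test_that("simplified xi closed forms evaluate as printed", {
  xs <- xi_simplified(0.5, 0.03, fx$membrane, c1bar = 2, c2bar = 37.71)
  f <- (0.5 - 0.03) / (0.5 * 0.03)
  expect_equal(xs$xi[2, 1], -f)           # -31.33
  expect_equal(xs$xi[2, 1], -31.33, tolerance = 1e-3)
  expect_equal(xs$xi[2, 2], -xs$xi[2, 1])
  expect_equal(xs$xi[3, 1], xs$xi[2, 1])
  expect_equal(xs$xi[1, 2], f / (1 - 0.068))
  expect_equal(xs$xi[1, 3], f / (1 - 0.025))
  expect_equal(xs$xi_det, (0.5^2 - 0.03^2) / (0.5^2 * 0.03^2))
  xe <- xi_simplified(0.4, 0.4, fx$membrane, 2, 37.71)
  expect_true(all(xe$xi == 0))
  expect_identical(xe$xi_det, 0)
  expect_error(xi_simplified(0, 0.5, fx$membrane, 2, 37.71), "\\(0, 1]")
})

test_that("full and simplified xi magnitudes agree for the reduced model", {
  # the simplified forms neglect the cross-permeabilities; for this membrane
  # that costs well under 5% in magnitude (the matrix form is authoritative
  # for the sign)
  zb <- 0.5
  for (za in seq(0.05, 0.95, by = 0.1)) {
    m <- list(
      A = rform_matrix(fx$membrane, cp_reduced(za, za, "A"), 5, 37.71),
      B = rform_matrix(fx$membrane, cp_reduced(zb, zb, "B"), 5, 37.71),
      hom = rform_matrix(fx$membrane, cp_homogeneous(), 5, 37.71))
    full <- xi_coefficients(m$A, m$B, m$hom)
    simp <- xi_simplified(za, zb, fx$membrane, 5, 37.71)
    expect_equal(abs(full$xi), abs(simp$xi), tolerance = 0.05)
    expect_equal(abs(full$xi_det), abs(simp$xi_det), tolerance = 0.05)
  }
})

test_that("boundary-layer factors are consistent with direct zeta arithmetic", {
  expect_identical(
    unname(zeta_difference_factors(0.4, 0.4, 0.8e-9, 0.69e-9, env0)),
    c(0, 0))
  set.seed(51)
  for (k in 1:20) {
    za <- stats::runif(1, 0.05, 1); zb <- stats::runif(1, 0.05, 1)
    fac <- zeta_difference_factors(za, zb, 0.8e-9, 0.69e-9, env0)
    expect_equal(fac[["linear"]], (za - zb) / (za * zb), tolerance = 1e-10)
    expect_equal(fac[["quadratic"]], (za^2 - zb^2) / (za * zb)^2,
                 tolerance = 1e-10)
  }
  # frozen closed-form value: fixture omega11/D11, layer gap
  # delta_B - delta_A = 3.43e-3 m at T = 298.15 K
  za <- zeta_from_delta(0.8e-9, 0.69e-9, 0.52e-3, env = env0)
  zb <- zeta_from_delta(0.8e-9, 0.69e-9, 3.95e-3, env = env0)
  fac <- zeta_difference_factors(za, zb, 0.8e-9, 0.69e-9, env0)
  expect_equal(fac[["linear"]], 19.716, tolerance = 1e-3)
})

test_that("sign classification reproduces the criteria table pattern", {
  # below the crossing every xi entry is negative (upward convection),
  # above it positive (downward)
  below <- profile_matrices(2)
  xb <- xi_coefficients(below$A, below$B, below$hom)
  tb <- classify_signs(xb, below$A, below$B, below$hom)
  expect_true(all(tb$xi_sign == "negative"))
  expect_true(all(tb$interpretation == "convection_up"))
  expect_identical(tb$ordering[tb$entry == "11"], "A<B")   # R11 > 0 row
  expect_identical(tb$ordering[tb$entry == "12"], "A>B")   # R12 < 0 row
  above <- profile_matrices(15)
  ta <- classify_signs(xi_coefficients(above$A, above$B, above$hom),
                       above$A, above$B, above$hom)
  expect_true(all(ta$xi_sign == "positive"))
  expect_true(all(ta$interpretation == "convection_down"))
  crit <- profile_matrices(9.24)
  tc <- classify_signs(xi_coefficients(crit$A, crit$B, crit$hom),
                       crit$A, crit$B, crit$hom)
  expect_true(all(tc$xi_sign == "zero"))
  expect_true(all(tc$ordering == "A=B"))
})
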