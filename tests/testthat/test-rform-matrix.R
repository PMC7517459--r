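test_that("homogeneous coefficients reproduce the published magnitudes", {
  R <- rform_matrix(fx$membrane, cp_homogeneous(), 1.44, 37.71)
  expect_equal(R$entries[1, 1], 2.31e11, tolerance = 5e-3)
  expect_equal(R$entries[1, 2], -1.16e9, tolerance = 1e-2)
  expect_equal(R$entries[1, 3], -0.68e9, tolerance = 1e-2)
  # R12 and R13 do not depend on the concentrations
  R2 <- rform_matrix(fx$membrane, cp_homogeneous(), 21.67, 37.71)
  expect_identical(R$entries[1, 2], R2$entries[1, 2])
  expect_identical(R$entries[1, 3], R2$entries[1, 3])
  expect_equal(R2$entries[1, 1], 2.53e11, tolerance = 5e-3)
})

test_that("strict-inverse entries equal the numerical inversion oracle", {
  set.seed(41)
  for (k in 1:20) {
    membrane <- random_membrane()
    zeta1 <- stats::runif(1, 0.03, 1)
    zeta2 <- stats::runif(1, 0.03, 1)
    cp <- cp_reduced(zeta1, zeta2, "A")
    C1l <- stats::runif(1, 0.2, 1)
    baths <- bath_state(C1h = stats::runif(1, 0.5, 25) * 3 + C1l, C1l = C1l,
                        C2h = 201, C2l = 1)
    R <- rform_matrix(membrane, cp, baths$c1bar, baths$c2bar,
                      variant = "strict_inverse")
    O <- invert_conductance_oracle(membrane, cp, baths)
    expect_equal(unname(R$entries), unname(O), tolerance = 1e-10)
  }
})

test_that("printed and strict variants differ only by the concentration rescaling", {
  cp <- cp_reduced(0.3, 0.6, "A")
  Rp <- rform_matrix(fx$membrane, cp, 5, 37.71, variant = "as_printed")
  Rs <- rform_matrix(fx$membrane, cp, 5, 37.71, variant = "strict_inverse")
  expect_equal(Rp$entries[2, 1] / 5, Rs$entries[2, 1])
  expect_equal(Rp$entries[3, 1] / 37.71, Rs$entries[3, 1])
  same <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 2),
                c(3, 3))
  for (k in seq_len(nrow(same)))
    expect_identical(Rp$entries[same[k, 1], same[k, 2]],
                     Rs$entries[same[k, 1], same[k, 2]])
})

test_that("polarized formulas collapse exactly to the homogeneous ones at zeta = 1", {
  set.seed(42)
  for (k in 1:10) {
    membrane <- random_membrane()
    c1 <- stats::runif(1, 0.5, 25); c2 <- stats::runif(1, 5, 100)
    a <- rform_matrix(membrane, cp_reduced(1, 1, "A"), c1, c2)
    h <- rform_matrix(membrane, cp_homogeneous(), c1, c2)
    expect_identical(unname(a$entries), unname(h$entries))
    expect_identical(a$det, h$det)
  }
})

test_that("determinant: closed form, brute force and sign rule agree", {
  cp <- cp_reduced(0.4, 0.7, "B")
  R <- rform_matrix(fx$membrane, cp, 9.24, 37.71)
  expect_equal(R$det, det(R$entries), tolerance = 1e-8)
  closed <- 1 / (fx$membrane$Lp * 9.24 * 37.71 * R$gamma_zeta)
  expect_equal(R$det, closed, tolerance = 1e-12)
  expect_gt(R$det, 0)  # gamma_zeta > 0 branch
  # homogeneous fixture value frozen from the closed form
  Rh <- rform_matrix(fx$membrane, cp_homogeneous(), 1.44, 37.71)
  expect_equal(Rh$det, 3.285e27, tolerance = 1e-3)
  # negative permeability determinant flips the sign
  m_neg <- membrane_coefficients(1e-12, 0.1, 0.1, omega11 = 1e-10,
                                 omega12 = 8e-10, omega21 = 8e-10,
                                 omega22 = 1e-10)
  Rn <- rform_matrix(m_neg, cp_homogeneous(), 2, 30)
  expect_lt(Rn$det, 0)
  expect_equal(Rn$det, det(Rn$entries), tolerance = 1e-8)
  # scaling c1bar by k scales the strict determinant by 1/k
  R2 <- rform_matrix(fx$membrane, cp, 2 * 9.24, 37.71)
  expect_equal(R2$det, R$det / 2, tolerance = 1e-12)
})

test_that("a zeta-weighted singular permeability determinant raises a typed error", {
  membrane <- membrane_coefficients(1e-12, 0.1, 0.1, omega11 = 2e-9,
                                    omega12 = 1.9e-9, omega21 = 1.9e-9,
                                    omega22 = 2e-9)
  cp <- cp_coefficients(zeta_s11 = 0.95, zeta_s22 = 0.95,
                        zeta_s12 = 1, zeta_s21 = 1, configuration = "A")
  expect_error(rform_matrix(membrane, cp, 5, 30),
               class = "kkp_singularity_error")
  expect_error(rform_matrix(membrane, cp, 5, 30), "omega11")
})

test_that("concentration polarization breaks Onsager reciprocity", {
  cp <- cp_reduced(0.5, 0.03, "A")  # zeta1 != zeta2
  R <- rform_matrix(fx$membrane, cp, 2, 37.71, variant = "strict_inverse")
  expect_gt(abs(R$entries[1, 2] - R$entries[2, 1]) /
              abs(R$entries[1, 2]), 0.01)
})

test_that("A and B entries computed from the published profiles agree at the crossing", {
  m <- profile_matrices(9.24)
  expect_equal(unname(m$A$entries), unname(m$B$entries), tolerance = 1e-10)
  expect_equal(m$A$det, m$B$det, tolerance = 1e-10)
})
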