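# Shared fixtures and random parameter draws for the test suite.

fx <- nephrophan_fixture()

# A physically plausible random membrane: reflection coefficients below 1,
# cross-permeabilities small relative to the geometric mean of the diagonal
# permeabilities (the regime of the studied system, and the regime in which
# passive transport keeps the coupling degrees bounded by 1).
random_membrane <- function() {
  w11 <- 10^stats::runif(1, -10, -8.5)
  w22 <- 10^stats::runif(1, -10, -8.5)
  wg <- sqrt(w11 * w22)
  membrane_coefficients(
    Lp = 10^stats::runif(1, -12.5, -11),
    sigma1 = stats::runif(1, 0, 0.95),
    sigma2 = stats::runif(1, 0, 0.95),
    omega11 = w11,
    omega12 = stats::runif(1, 0, 0.05) * wg,
    omega21 = stats::runif(1, 0, 0.05) * wg,
    omega22 = w22)
}

random_cp <- function(configuration = "A") {
  cp_reduced(stats::runif(1, 0.03, 1), stats::runif(1, 0.03, 1),
             configuration)
}

# Second-law check: the symmetric part of the conductance map must be
# positive semidefinite (non-negative dissipation for every force vector).
# Parameter draws violating it are unphysical and rejected.
is_passive <- function(membrane, cp, baths) {
  L <- vapply(seq_len(3L), function(j) {
    X <- numeric(3L); X[j] <- 1
    kk_fluxes_from_forces(membrane, cp, X, baths$c1bar, baths$c2bar)
  }, numeric(3L))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -1e-12 * max(abs(ev)))
}

# A random parameter set (membrane, polarization, baths) satisfying the
# second law.
random_passive_system <- function() {
  repeat {
    sys <- list(membrane = random_membrane(), cp = random_cp(),
                baths = random_baths())
    if (is_passive(sys$membrane, sys$cp, sys$baths)) return(sys)
  }
}

random_baths <- function() {
  C1l <- stats::runif(1, 0.5, 2)
  C2l <- stats::runif(1, 0.5, 2)
  bath_state(C1h = C1l + stats::runif(1, 0.5, 80), C1l = C1l,
             C2h = C2l + stats::runif(1, 10, 300), C2l = C2l,
             dP = stats::runif(1, -5e3, 5e3))
}

# Resistance matrices of both configurations plus the homogeneous case at
# one sweep point, using the published zeta profiles.
profile_matrices <- function(c1bar, c2bar = 37.71,
                             membrane = fx$membrane,
                             variant = "strict_inverse") {
  pr <- nephrophan_zeta_profiles()
  zA <- evaluate_profile(pr$A, c1bar)
  zB <- evaluate_profile(pr$B, c1bar)
  list(A = rform_matrix(membrane, cp_reduced(zA, zA, "A"), c1bar, c2bar,
                        variant = variant),
       B = rform_matrix(membrane, cp_reduced(zB, zB, "B"), c1bar, c2bar,
                        variant = variant),
       hom = rform_matrix(membrane, cp_homogeneous(), c1bar, c2bar,
                          variant = variant))
}
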