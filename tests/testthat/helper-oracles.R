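# Independent oracles used across the suite.  These never call the
# package's integrator: linear schemes are solved by eigendecomposition,
# binding equilibria by the quadratic formula, Lorentzian integrals in
# closed form.

# Solve dy/dt = M y by matrix exponential (eigendecomposition).
linear_ode_oracle <- function(M, y0, times) {
  eg <- eigen(M)
  V <- eg$vectors
  c0 <- solve(V, y0)
  out <- vapply(times, function(t) Re(V %*% (c0 * exp(eg$values * t))),
                numeric(length(y0)))
  t(out)
}

# Rate matrix of a purely unimolecular kinetic_scheme.
rate_matrix_of <- function(scheme) {
  n <- length(scheme$species)
  M <- matrix(0, n, n, dimnames = list(scheme$species, scheme$species))
  for (st in scheme$reactions) {
    stopifnot(length(st$reactants) == 1L)
    k <- scheme$rate_constants[[st$rate]]
    r <- st$reactants
    M[r, r] <- M[r, r] - k
    for (p in st$products) M[p, r] <- M[p, r] + k
  }
  M
}

# 1:1 binding equilibrium, quadratic formula.
quadratic_bound <- function(E0, L0, KD) {
  b <- E0 + L0 + KD
  (b - sqrt(b^2 - 4 * E0 * L0)) / 2
}

# Fraction of a unit-area Lorentzian (FWHM fwhm) inside +/- halfwindow.
lorentz_window_fraction <- function(halfwindow, fwhm) {
  (2 / pi) * atan(halfwindow / (fwhm / 2))
}

# Brute-force macroscopic K_D: free-ligand concentration at half-saturation
# of all bound forms, found by equilibrium titration of the full scheme.
titration_midpoint_kd <- function(params) {
  kd_guess <- macroscopic_kd(params)
  E0 <- kd_guess * 1e-4
  sc <- binding_scheme(params)
  has_if <- !is.null(params$k_if)
  p_act <- 1 / (1 + params$k_ai / params$k_ia)
  bound_frac <- function(Ltot) {
    init <- c(I = E0 * (1 - p_act), A = E0 * p_act, L = Ltot, AL = 0)
    if (has_if) init <- c(init, ALs = 0)
    eq <- equilibrium_state(sc, init = init)
    (eq[["AL"]] + if (has_if) eq[["ALs"]] else 0) / E0
  }
  u <- stats::uniroot(function(L) bound_frac(L) - 0.5,
                      lower = kd_guess / 100, upper = kd_guess * 100,
                      tol = kd_guess * 1e-7)
  u$root - 0.5 * E0   # total -> free ligand at the midpoint
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
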