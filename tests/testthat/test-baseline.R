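test_that("analytic baselines reproduce their closed-form spectra", {
  bl <- analytic_baseline(harmonic_sys(), 3)
  expect_equal(bl$energies, c(0.5, 1.5, 2.5))
  # baseline states evaluate to constant local energies (exact init)
  X <- matrix(rnorm(400), ncol = 1)
  for (k in 1:3) {
    el <- local_energy(bl$states[[k]], harmonic_sys(), X)
    expect_lt(var(el), 1e-10)
    expect_equal(mean(el), bl$energies[k], tolerance = 1e-8)
  }
  # mutual overlaps are zero by orthonormality
  grid <- default_grid()
  expect_lt(abs(quadrature_observable(op_identity(), bl$states[[1]],
                                      bl$states[[2]], grid)), 1e-8)
  blh <- analytic_baseline(hydrogen_sys(), 2)
  expect_equal(blh$energies, c(-0.5, -0.125))
  expect_error(analytic_baseline(hydrogen_sys(), 9), "available")
})

test_that("grid-provider baselines agree with the closed forms", {
  bl <- analytic_baseline(harmonic_sys(), 2, provider = "grid")
  expect_equal(bl$energies, c(0.5, 1.5), tolerance = 1e-8)
})

test_that("determinant truncation keeps the largest coefficients stably", {
  sel <- select_determinants(list(c(0.9, -0.5, 0.1)), 2)[[1]]
  expect_equal(sel$index, c(1L, 2L))
  expect_equal(sel$coefs, c(0.9, -0.5) / sqrt(0.9^2 + 0.5^2))
  # max_dets beyond length: all kept, re-sorted by |c|
  sel2 <- select_determinants(list(c(0.2, -0.9, 0.5)), 10)[[1]]
  expect_equal(sel2$index, c(2L, 3L, 1L))
  expect_equal(sum(sel2$coefs^2), 1)
  # ties broken by original index, checked against a brute-force sort
  cf <- c(0.5, -0.5, 0.3, 0.5)
  sel3 <- select_determinants(list(cf), 3)[[1]]
  brute <- order(-abs(cf), seq_along(cf))[1:3]
  expect_equal(sel3$index, brute)
  # retained coefficient mass is non-decreasing in max_dets
  cf2 <- c(0.6, 0.5, -0.4, 0.3, 0.2, 0.1)
  mass <- vapply(1:6, function(m) {
    keep <- select_determinants(list(cf2), m)[[1]]$index
    sum(cf2[keep]^2) / sum(cf2^2)
  }, numeric(1))
  expect_true(all(diff(mass) >= 0))
})

# an even-tempered Gaussian expansion of the hydrogen ground state, built
# and orthonormalized in code: the imported baseline must land within a
# few mHa of the exact -0.5 Ha
hydrogen_payload <- function() {
  expo <- 0.05 * 3^(0:5)
  basis <- lapply(expo, function(a) list(type = "gauss_s",
                                         center = c(0, 0, 0), exponent = a))
  # overlap and hamiltonian matrices for s Gaussians (closed forms)
  Sst <- outer(expo, expo, function(a, b) (pi / (a + b))^1.5)
  Tm <- outer(expo, expo, function(a, b) 3 * a * b * pi^1.5 / (a + b)^2.5)
  Vm <- outer(expo, expo, function(a, b) -2 * pi / (a + b))
  H <- Tm + Vm
  ge <- eigen(solve(Sst, H))
  ord <- order(Re(ge$values))
  coefs <- Re(ge$vectors[, ord[1:2]])
  for (k in 1:2) {
    nrm <- sqrt(drop(t(coefs[, k]) %*% Sst %*% coefs[, k]))
    coefs[, k] <- coefs[, k] / nrm
  }
  list(
    basis = basis,
    mo_coeffs = t(coefs),
    states = list(
      list(dets = list(list(up = 1, down = integer(0))), coefs = 1),
      list(dets = list(list(up = 2, down = integer(0))), coefs = 1)
    ),
    active_space = list(electrons = 1, orbitals = 2)
  )
}

test_that("imported baselines build evaluable cusped ansatzes", {
  hs <- hydrogen_sys()
  pl <- hydrogen_payload()
  bl <- import_casscf(pl, hs, 2, jastrow = FALSE, backflow = FALSE,
                      ortho_tol = 1e-6)
  expect_equal(bl$n_states, 2)
  wf0 <- bl$states[[1]]
  # exact expectations over a radial quadrature cloud (s states)
  r <- seq(1e-3, 45, length.out = 3000)
  qb <- config_batch(cbind(0, 0, r), log_base = -log(4 * pi * r^2 * (r[2] - r[1])))
  est <- energy_estimate(wf0, hs, qb)
  # even-tempered 6-Gaussian expansion with the cusp envelope attached
  expect_lt(abs(est$value - (-0.5)), 5e-3)
  # the two imported states start with a small overlap
  S <- overlap_estimate(bl$states[[1]], bl$states[[2]], qb, qb,
                        cap_quantile = 1)
  expect_lt(abs(S$value), 0.1)
})

test_that("non-orthonormal imports are rejected; JSON round-trips", {
  hs <- hydrogen_sys()
  pl <- hydrogen_payload()
  bad <- pl
  bad$mo_coeffs[1, ] <- bad$mo_coeffs[1, ] * 1.5
  expect_error(import_casscf(bad, hs, 2, jastrow = FALSE, backflow = FALSE),
               "orthonormal")
  # JSON round trip reproduces the same ansatz bit-exactly
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(pl, path, auto_unbox = TRUE, digits = I(17))
  bl1 <- import_casscf(pl, hs, 1, jastrow = FALSE, backflow = FALSE)
  bl2 <- import_casscf(path, hs, 1, jastrow = FALSE, backflow = FALSE)
  X <- matrix(rnorm(30), ncol = 3)
  expect_identical(psi_eval(bl1$states[[1]], X)$logabs,
                   psi_eval(bl2$states[[1]], X)$logabs)
})

test_that("missing CI vectors raise a configuration error", {
  expect_error(import_casscf(hydrogen_payload(), hydrogen_sys(), 5),
               "state")
})
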