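# Frozen closed-form references used below:
#   variational energy of psi = exp(-a r) on hydrogen: a^2/2 - a
#   harmonic matrix elements (omega = 1): <0|x|1> = 1/sqrt(2), <0|x|2> = 0
#   mixture overlaps: <psi_0 | psi_eps> = sqrt(eps)

test_that("energy estimate has zero variance at an eigenstate", {
  wf <- harmonic_eigenstate(0)
  sys1 <- harmonic_sys()
  est <- energy_estimate(wf, sys1, config_batch(matrix(rnorm(500), ncol = 1)))
  expect_equal(est$value, 0.5, tolerance = 1e-12)
  expect_lt(est$se, 1e-10)
  expect_lt(est$variance, 1e-10)
})

test_that("hydrogen exp(-a r) reproduces its closed-form variational energy", {
  a <- 0.8
  wf <- radial_poly_wavefunction(1, alpha = a)
  hs <- hydrogen_sys()
  ens <- init_walkers(wf, hs, 4000, seed = 2, burn = 400)
  est <- energy_estimate(wf, hs, ens)
  expect_within_3se(est$value, est$se, a^2 / 2 - a)   # -0.48 Ha
})

test_that("trained-or-not, box energies respect the variational bound", {
  box <- model_system("box", box_length = 1)
  sol <- grid_eigensolve(box, 1, n = 1501)
  # a deliberately imperfect state: the exact n=2 box state mixed up
  wf <- box_eigenstate(1, 1)
  ens <- init_walkers(wf, box, 2000, seed = 3, burn = 200, step = 0.1)
  est <- energy_estimate(wf, box, ens)
  expect_gt(est$value, sol$energies[1] - 3 * max(est$se, 1e-10) - 1e-8)
})

test_that("overlap estimator calibrates against exact mixtures", {
  sys1 <- harmonic_sys()
  wf0 <- harmonic_eigenstate(0)
  ens0 <- init_walkers(wf0, sys1, 4000, seed = 5, burn = 300)
  for (eps in c(0.04, 0.25)) {
    fx <- make_mixture(eps, wf0, harmonic_eigenstate(1))
    ensm <- init_walkers(fx$wf, sys1, 4000, seed = 50 + round(100 * eps),
                         burn = 400)
    S <- overlap_estimate(fx$wf, wf0, ensm, ens0)
    expect_within_3se(S$value, S$se, sqrt(eps))
  }
})

test_that("overlap is exactly norm-free and S_ii = 1", {
  wf <- random_poly_gauss(21)
  scaled <- scaled_wavefunction(wf, 3)
  sys1 <- harmonic_sys()
  ens <- init_walkers(wf, sys1, 1000, seed = 8, burn = 200)
  b <- batch_from_ensemble(ens)
  S_self <- overlap_estimate(wf, wf, b, b)
  expect_identical(S_self$value, 1)
  # scale cancels bit-exactly in the log domain
  S_scaled <- overlap_estimate(wf, scaled, b, b)
  expect_equal(S_scaled$value, 1, tolerance = 1e-12)
  ens2 <- init_walkers(random_poly_gauss(22), sys1, 1000, seed = 9, burn = 200)
  b2 <- batch_from_ensemble(ens2)
  s1 <- overlap_estimate(random_poly_gauss(22), wf, b2, b)
  s2 <- overlap_estimate(scaled_wavefunction(random_poly_gauss(22), 7),
                         scaled, b2, b)
  expect_equal(s1$value, s2$value, tolerance = 1e-12)
})

test_that("hydrogen 1s and 2p_z are reported orthogonal", {
  hs <- hydrogen_sys()
  s1 <- hydrogenic_state("1s")
  pz <- hydrogenic_state("2pz")
  e1 <- init_walkers(s1, hs, 4000, seed = 11, burn = 300)
  e2 <- init_walkers(pz, hs, 4000, seed = 12, burn = 400)
  S <- overlap_estimate(s1, pz, e1, e2)
  expect_lt(abs(S$value), 3 * max(S$se, 1e-3))
})

test_that("mixed observable with identity equals the overlap bit-exactly", {
  sys1 <- harmonic_sys()
  wf_a <- random_poly_gauss(31)
  wf_b <- random_poly_gauss(32)
  ba <- batch_from_ensemble(init_walkers(wf_a, sys1, 800, seed = 13, burn = 150))
  bb <- batch_from_ensemble(init_walkers(wf_b, sys1, 800, seed = 14, burn = 150))
  mo <- mixed_observable(op_identity(), wf_a, wf_b, ba, bb)
  ov <- overlap_estimate(wf_a, wf_b, ba, bb)
  expect_identical(mo$value, ov$value)
})

test_that("mixed observable recovers closed-form position matrix elements", {
  sys1 <- harmonic_sys()
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  b0 <- init_walkers(wf0, sys1, 6000, seed = 15, burn = 300)
  b1 <- init_walkers(wf1, sys1, 6000, seed = 16, burn = 400)
  opx <- op_multiply(function(X) X[, 1], name = "x")
  m01 <- mixed_observable(opx, wf0, wf1, b0, b1)
  expect_within_3se(abs(m01$value), m01$se, 1 / sqrt(2))
  # parity: <1s| x |1s> = 0 on hydrogen
  hs <- hydrogen_sys()
  s1 <- hydrogenic_state("1s")
  bh <- init_walkers(s1, hs, 4000, seed = 17, burn = 300)
  mx <- mixed_observable(op_dipole(hs, 1, q = 1), s1, s1, bh, bh)
  expect_lt(abs(mx$value), 3 * max(mx$se, 1e-3))
})

test_that("i = j with the Hamiltonian reduces to the energy estimate", {
  sys1 <- harmonic_sys()
  wf <- random_poly_gauss(41)
  b <- batch_from_ensemble(init_walkers(wf, sys1, 1500, seed = 18, burn = 200))
  mo <- mixed_observable(op_hamiltonian(sys1), wf, wf, b, b, cap_quantile = 1)
  ee <- energy_estimate(wf, sys1, b)
  expect_equal(mo$value, ee$value, tolerance = 1e-12)
})

test_that("transition dipoles obey parity and selection rules", {
  sys1 <- harmonic_sys()
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  wf2 <- harmonic_eigenstate(2)
  b0 <- init_walkers(wf0, sys1, 6000, seed = 19, burn = 300)
  b1 <- init_walkers(wf1, sys1, 6000, seed = 20, burn = 400)
  b2 <- init_walkers(wf2, sys1, 6000, seed = 21, burn = 400)
  # 0 <-> 1 with q = -1: |d| = 1/sqrt(2), d^2 = 1/2
  tm <- transition_dipole(wf0, wf1, b0, b1, sys1, delta_e = 1)
  expect_within_3se(abs(tm$d[1]), tm$d_se[1], 1 / sqrt(2))
  # same parity 0 <-> 2: selection rule gives 0
  tm02 <- transition_dipole(wf0, wf2, b0, b2, sys1, delta_e = 2)
  expect_lt(abs(tm02$d[1]), 3 * max(tm02$d_se[1], 1e-3))
  # i = j on a centrosymmetric state: zero vector
  tm00 <- transition_dipole(wf0, wf0, b0, b0, sys1, delta_e = 0)
  expect_lt(abs(tm00$d[1]), 3 * max(tm00$d_se[1], 1e-3))
})

test_that("oscillator strength is the stated arithmetic", {
  expect_equal(oscillator_strength(delta_e = 1, d2 = 3), 2)
  expect_equal(oscillator_strength(delta_e = 5, d2 = 0), 0)
  f <- oscillator_strength(delta_e = -0.5, d2 = 1)
  expect_equal(as.numeric(f), -1 / 3)
  expect_match(attr(f, "flagged"), "negative")
})

test_that("estimators agree with quadrature across random ansatz pairs", {
  grid <- default_grid()
  qb <- quadrature_batch(grid)
  for (seed in 1:6) {
    wf_a <- random_poly_gauss(100 + seed)
    wf_b <- random_poly_gauss(200 + seed)
    S_mc <- overlap_estimate(wf_a, wf_b, qb, qb, cap_quantile = 1)
    S_q <- quadrature_observable(op_identity(), wf_a, wf_b, grid)
    expect_equal(S_mc$value, S_q, tolerance = 1e-8)
  }
})
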