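test_that("grid eigensolver reproduces closed-form spectra", {
  harm <- grid_eigensolve(harmonic_sys(), 3, n = 1601)
  expect_equal(harm$energies, c(0.5, 1.5, 2.5), tolerance = 1e-6)
  box <- grid_eigensolve(model_system("box", box_length = 1), 2, n = 2001)
  expect_equal(box$energies, (1:2)^2 * pi^2 / 2, tolerance = 1e-6)
  rad <- grid_eigensolve(hydrogen_sys(), 2, n = 4001)
  expect_equal(rad$energies, c(-0.5, -0.125), tolerance = 1e-3)
  expect_lt(abs(rad$energies[1] + 0.5), 1e-4)
  expect_lt(abs(rad$energies[2] + 0.125), 1e-4)
  # eigenvalues non-decreasing, eigenfunctions quadrature-orthonormal
  expect_true(!is.unsorted(harm$energies))
  G <- t(harm$states) %*% (harm$weights * harm$states)
  expect_equal(G, diag(3), tolerance = 1e-8)
})

test_that("eigenvalue error decreases monotonically under grid refinement", {
  errs <- vapply(c(201, 401, 801), function(n) {
    abs(grid_eigensolve(harmonic_sys(), 1, n = n)$energies[1] - 0.5)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("insufficient grid extent is refused with diagnostics", {
  expect_error(grid_eigensolve(harmonic_sys(), 3, n = 201, extent = 2.5),
               "boundary mass")
})

test_that("two-particle grids respect the requested exchange sector", {
  sys2 <- model_system("harmonic", n_particles = 2, n_up = 1)
  sym <- grid_eigensolve(sys2, 2, n = 41, symmetry = "symmetric")
  anti <- grid_eigensolve(sys2, 2, n = 41, symmetry = "antisymmetric")
  # non-interacting: symmetric ground 1.0; antisymmetric ground 2.0
  expect_equal(sym$energies[1], 1.0, tolerance = 2e-2)
  expect_equal(anti$energies[1], 2.0, tolerance = 5e-2)
  expect_gt(anti$energies[1], sym$energies[1])
  # interaction raises both sector energies
  sys2i <- model_system("harmonic", n_particles = 2, n_up = 1,
                        interaction = TRUE, soft = 1)
  symi <- grid_eigensolve(sys2i, 1, n = 41, symmetry = "symmetric")
  expect_gt(symi$energies[1], sym$energies[1])
})

test_that("mixture fixtures carry their exact overlap and energy", {
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  grid <- default_grid()
  for (eps in c(0, 0.04, 0.25, 1)) {
    fx <- make_mixture(eps, wf0, wf1)
    expect_equal(fx$overlap0, sqrt(eps))
    S <- quadrature_observable(op_identity(), wf0, fx$wf, grid)
    expect_equal(S, sqrt(eps), tolerance = 1e-8)
    E <- quadrature_observable(op_hamiltonian(harmonic_sys()), fx$wf, fx$wf,
                               grid)
    expect_equal(E, (1 - eps) * 1.5 + eps * 0.5, tolerance = 1e-7)
  }
  # non-orthonormal inputs rejected
  expect_error(make_mixture(0.1, wf0, scaled_wavefunction(wf1, 2)),
               "orthonormal")
  expect_error(make_mixture(0.1, wf0, wf0), "orthonormal")
})

test_that("quadrature matrix elements reproduce closed forms", {
  grid <- default_grid()
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  expect_equal(quadrature_observable(op_identity(), wf0, wf1, grid), 0,
               tolerance = 1e-8)
  expect_equal(quadrature_observable(op_identity(), wf1, wf1, grid), 1,
               tolerance = 1e-8)
  opx <- op_multiply(function(X) X[, 1])
  expect_equal(abs(quadrature_observable(opx, wf0, wf1, grid)), 1 / sqrt(2),
               tolerance = 1e-6)
})

test_that("the penalized loss over the mixture sweep is minimized at eps = 0", {
  # brute-force sweep of loss(eps) = E(eps) + alpha * penalty(sqrt(eps)):
  # for alpha above a computable threshold the optimum sits at the
  # orthogonal solution, so penalty training cannot gain by mixing
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  eps_grid <- seq(0, 1, length.out = 201)
  E <- (1 - eps_grid) * 1.5 + eps_grid * 0.5
  for (alpha in c(0.5, 1, 2)) {
    loss <- E + alpha * overlap_penalty(sqrt(eps_grid))
    expect_equal(which.min(loss), 1L)
  }
  # and a tiny alpha below the threshold lets mixing win (sanity check of
  # the threshold's existence)
  loss_small <- E + 0.02 * overlap_penalty(sqrt(eps_grid))
  expect_gt(which.min(loss_small), 1L)
})

test_that("grid eigenfunctions round-trip through the wavefunction wrapper", {
  sol <- grid_eigensolve(harmonic_sys(), 2, n = 1201)
  wf <- grid_state_wavefunction(sol, 2)
  x <- seq(-3, 3, length.out = 101)
  e <- psi_eval(wf, matrix(x, ncol = 1))
  exact <- psi_eval(harmonic_eigenstate(1), matrix(x, ncol = 1))
  expect_equal(e$sign * exp(e$logabs), exact$sign * exp(exact$logabs),
               tolerance = 1e-4)
})
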