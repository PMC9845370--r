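# The finite-difference oracles use a frozen common point cloud carrying
# its base density: on a shared weighted point set the covariance-form
# gradients are the exact derivatives of the corresponding estimators, so
# central differences must match to truncation error.

fd_quadrature <- function(f, wf, theta, h = 1e-5) {
  vapply(seq_along(theta), function(k) {
    t1 <- theta; t1[k] <- t1[k] + h
    t2 <- theta; t2[k] <- t2[k] - h
    (f(wf_set_params(wf, t1)) - f(wf_set_params(wf, t2))) / (2 * h)
  }, numeric(1))
}

test_that("energy gradient matches central differences on a common cloud", {
  sys1 <- harmonic_sys()
  qb <- quadrature_batch(default_grid())
  for (seed in c(2, 7)) {
    wf <- random_poly_gauss(seed)
    g <- grad_energy(wf, sys1, qb, winsor_k = Inf, pgrad_cap = 1)
    fd <- fd_quadrature(function(w) energy_estimate(w, sys1, qb)$value,
                        wf, wf_params(wf))
    expect_equal(unname(as.numeric(g)), fd, tolerance = 1e-4)
  }
})

test_that("overlap gradient matches central differences on a common cloud", {
  qb <- quadrature_batch(default_grid())
  wf_i <- random_poly_gauss(3)   # 2-parameter pairs below freeze the rest
  wf_j <- random_poly_gauss(4)
  go <- grad_overlap(wf_i, wf_j, qb, qb, cap_quantile = 1, pgrad_cap = 1,
                     se_gate = 0)
  S_of <- function(w_i, w_j) {
    overlap_estimate(w_i, w_j, qb, qb, cap_quantile = 1)$value
  }
  fd_i <- fd_quadrature(function(w) S_of(w, wf_j), wf_i, wf_params(wf_i))
  fd_j <- fd_quadrature(function(w) S_of(wf_i, w), wf_j, wf_params(wf_j))
  expect_equal(unname(go$grad_i), fd_i, tolerance = 1e-4)
  expect_equal(unname(go$grad_j), fd_j, tolerance = 1e-4)
  # detachment returns the state-i part only
  gd <- grad_overlap(wf_i, wf_j, qb, qb, detach_lower = TRUE,
                     cap_quantile = 1, pgrad_cap = 1, se_gate = 0)
  expect_identical(gd$grad_i, go$grad_i)
  expect_null(gd$grad_j)
})

test_that("i = j with the Hamiltonian reproduces the energy gradient bit-exactly", {
  sys1 <- harmonic_sys()
  wf <- random_poly_gauss(9)
  b <- batch_from_ensemble(init_walkers(wf, sys1, 800, seed = 5, burn = 150))
  go <- grad_overlap(wf, wf, b, b, op = op_hamiltonian(sys1))
  ge <- grad_energy(wf, sys1, b)
  expect_identical(go$grad_i, ge)
})

test_that("eigenstates give vanishing energy gradients", {
  sys1 <- harmonic_sys()
  wf <- harmonic_eigenstate(1)
  wf$free[] <- TRUE   # make the gradient visible
  b <- config_batch(matrix(rnorm(2000), ncol = 1))
  g <- grad_energy(wf, sys1, b)
  expect_lt(sqrt(sum(g^2)), 1e-8)
})

test_that("hydrogen exp(-a r) energy gradient matches the closed form", {
  # E(a) = a^2/2 - a, so dE/da = a - 1 and dE/dlog(a) = a(a - 1)
  a <- 0.8
  wf <- radial_poly_wavefunction(1, alpha = a)
  hs <- hydrogen_sys()
  ens <- init_walkers(wf, hs, 8000, seed = 6, burn = 400)
  b <- batch_from_ensemble(ens)
  g <- grad_energy(wf, hs, b, pgrad_cap = 1)[["log_alpha"]]
  # jackknife standard error of the gradient component
  el <- local_energy(wf, hs, b$X, check = FALSE)
  pg <- psi_pgrad(wf, b$X)[, "log_alpha"]
  se <- jackknife_se(function(i) 2 * mean((el[i] - mean(el[i])) * pg[i]),
                     seq_along(el), blocks = 20L)
  expect_within_3se(as.numeric(g), se, a * (a - 1))
})

test_that("pure normalization directions carry zero gradient", {
  # scaling all polynomial coefficients multiplies psi by a constant; the
  # directional derivative sum_k c_k dE/dc_k vanishes identically on any
  # common cloud (norm independence)
  sys1 <- harmonic_sys()
  qb <- quadrature_batch(default_grid())
  wf <- random_poly_gauss(13)
  g <- grad_energy(wf, sys1, qb, winsor_k = Inf, pgrad_cap = 1)
  coef <- wf_params(wf)[1:4]
  expect_lt(abs(sum(coef * g[1:4])), 1e-10)
  go <- grad_overlap(wf, random_poly_gauss(14), qb, qb, cap_quantile = 1,
                     pgrad_cap = 1, se_gate = 0)
  expect_lt(abs(sum(coef * go$grad_i[1:4])), 1e-10)
})

test_that("near-orthogonal pairs and tiny overlaps yield zero gradients", {
  qb <- quadrature_batch(default_grid())
  go <- grad_overlap(harmonic_eigenstate(0), harmonic_eigenstate(1), qb, qb,
                     cap_quantile = 1)
  expect_true(go$zeroed)
  expect_true(all(go$grad_i == 0))
})

test_that("winsorization and row caps touch only flagged samples", {
  sys1 <- harmonic_sys()
  wf <- poly_gauss_wavefunction(1, a = 1.2)   # node-free: benign tails
  b <- batch_from_ensemble(init_walkers(wf, sys1, 1000, seed = 8, burn = 150))
  g_raw <- grad_energy(wf, sys1, b, winsor_k = Inf, pgrad_cap = 1)
  g_soft <- grad_energy(wf, sys1, b, winsor_k = 50, pgrad_cap = 1)
  expect_equal(unname(g_raw), unname(g_soft), tolerance = 1e-12)
})
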