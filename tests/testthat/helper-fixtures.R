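# Shared fixtures, all built in code at test time.

harmonic_sys <- function(omega = 1) model_system("harmonic", omega = omega)

hydrogen_sys <- function() molecular_system(1, c(0, 0, 0), n_up = 1, n_down = 0)

# a smooth random 1D ansatz (degree-3 polynomial x Gaussian), non-node-free
random_poly_gauss <- function(seed, degree = 3) {
  set.seed(seed)
  poly_gauss_wavefunction(stats::rnorm(degree + 1, sd = c(1, rep(0.4, degree))),
                          a = exp(stats::rnorm(1, 0, 0.2)),
                          b = 0.2 * stats::rnorm(1))
}

# default 1D quadrature grid wide enough for all test ansatzes; an even
# node count avoids x = 0 (a common exact node of the test states)
default_grid <- function(n = 3000, ext = 12) seq(-ext, ext, length.out = n)

# a node-free smooth random 1D ansatz: quadratic with negative discriminant
nodeless_poly_gauss <- function(seed) {
  set.seed(seed)
  b <- stats::rnorm(1, 0, 0.4)
  c2 <- 0.2 + abs(stats::rnorm(1, 0, 0.3))
  c0 <- b^2 / (4 * c2) + 0.3 + abs(stats::rnorm(1, 0, 0.4))
  poly_gauss_wavefunction(c(c0, b, c2), a = exp(stats::rnorm(1, 0, 0.2)),
                          b = 0.2 * stats::rnorm(1))
}

# small He-like molecular ansatz with nontrivial Jastrow/backflow weights
random_sj_ansatz <- function(seed = 1, n_up = 1, n_down = 1, Z = 2,
                             jastrow = TRUE, backflow = TRUE) {
  sys <- molecular_system(Z, c(0, 0, 0), n_up = n_up, n_down = n_down)
  basis <- list(basis_function("gauss_s", exponent = 0.7),
                basis_function("gauss_s", exponent = 2.2),
                basis_function("gauss_pz", exponent = 1.1))
  oc <- matrix(c(1, 0.3, 0.1,
                 0.2, -0.8, 0.5,
                 0.1, 0.2, 0.9), 3, 3, byrow = TRUE)
  n_occ <- max(n_up, n_down)
  dets <- list(list(up = seq_len(n_up), down = seq_len(n_down)),
               list(up = c(seq_len(max(0, n_up - 1)), n_occ + 1L),
                    down = seq_len(n_down)))
  wf <- slater_jastrow_wavefunction(sys, basis, oc, dets,
                                    det_coefs = c(0.9, -0.4),
                                    jastrow = jastrow, backflow = backflow,
                                    width = 4, seed = seed)
  set.seed(seed + 100)
  wf_set_params(wf, wf_params(wf) + 0.1 * stats::rnorm(length(wf_params(wf))))
}

# antipodal direction pairs for spherically averaged coalescence probes
antipodal_dirs <- function(n, seed = 1) {
  set.seed(seed)
  d <- matrix(stats::rnorm(3 * n), n)
  d <- d / sqrt(rowSums(d^2))
  rbind(d, -d)
}

expect_within_3se <- function(est, se, truth, floor_se = 1e-12) {
  expect_lt(abs(est - truth), 3 * max(se, floor_se) + 1e-12)
}
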