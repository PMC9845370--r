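test_that("cusp envelope reproduces the Kato coalescence slopes", {
  eps <- 2e-5
  dirs <- antipodal_dirs(100, seed = 3)
  probe_slope <- function(sys, wf, base, mover) {
    # spherically averaged d ln|psi| / d(distance) between eps and 2 eps
    X1 <- X2 <- matrix(rep(base, nrow(dirs)), nrow(dirs), byrow = TRUE)
    X1[, mover] <- X1[, mover] + eps * dirs
    X2[, mover] <- X2[, mover] + 2 * eps * dirs
    mean((psi_eval(wf, X2)$logabs - psi_eval(wf, X1)$logabs) / eps)
  }
  # hydrogen, Z = 1: nuclear slope -1
  hw <- slater_jastrow_wavefunction(
    hydrogen_sys(), list(basis_function("gauss_s", exponent = 0.28)),
    matrix(1), list(list(up = 1L, down = integer(0))),
    jastrow = FALSE, backflow = FALSE
  )
  expect_equal(probe_slope(hydrogen_sys(), hw, c(0, 0, 0), 1:3), -1,
               tolerance = 1e-3)
  # helium, Z = 2 (second electron parked off-center)
  he <- molecular_system(2, c(0, 0, 0), 1, 1)
  hw2 <- slater_jastrow_wavefunction(
    he, list(basis_function("gauss_s", exponent = 0.9)), matrix(1),
    list(list(up = 1L, down = 1L)), jastrow = FALSE, backflow = FALSE
  )
  expect_equal(probe_slope(he, hw2, c(0, 0, 0, 1.2, 0, 0), 1:3), -2,
               tolerance = 1e-3)
  # opposite-spin pair coalescence at a point away from the nucleus: +1/2
  expect_equal(probe_slope(he, hw2, c(0.5, 0.3, -0.2, 0.5, 0.3, -0.2), 4:6),
               0.5, tolerance = 1e-3)
  # same-spin pair coalescence: +1/4 (two up electrons)
  li <- molecular_system(3, c(0, 0, 0), 2, 1)
  hw3 <- slater_jastrow_wavefunction(
    li, list(basis_function("gauss_s", exponent = 0.8),
             basis_function("gauss_pz", exponent = 0.8)),
    diag(2), list(list(up = c(1L, 2L), down = 1L)),
    jastrow = FALSE, backflow = FALSE
  )
  base <- c(0.6, 0.2, 0.4, 0.6, 0.2, 0.4, -0.8, 0.1, 0.2)
  # gamma alone isolates the pair slope (determinant varies too; use the
  # envelope directly)
  X1 <- X2 <- matrix(rep(base, nrow(dirs)), nrow(dirs), byrow = TRUE)
  X1[, 4:6] <- X1[, 4:6] + eps * dirs
  X2[, 4:6] <- X2[, 4:6] + 2 * eps * dirs
  slope <- mean((cusp_envelope(li, X2) - cusp_envelope(li, X1)) / eps)
  # contains the same-spin pair slope +1/4 plus smooth envelope curvature
  expect_equal(slope, 0.25, tolerance = 1e-3)
})

test_that("identity backflow leaves the bare orbital matrix unchanged", {
  sys <- molecular_system(2, c(0, 0, 0), 1, 1)
  basis <- list(basis_function("gauss_s", exponent = 0.7),
                basis_function("gauss_s", exponent = 2.0))
  oc <- matrix(c(1, 0.2, -0.3, 0.9), 2, 2, byrow = TRUE)
  wf <- slater_jastrow_wavefunction(sys, basis, oc,
                                    list(list(up = 1L, down = 1L)),
                                    jastrow = FALSE, backflow = TRUE,
                                    width = 4, seed = 2)
  conf <- c(0.3, -0.2, 0.5, -0.4, 0.6, -0.1)
  d <- dressed_orbitals(wf, conf)
  bare <- vapply(1:2, function(j) {
    r <- conf[(3 * j - 2):(3 * j)]
    as.vector(oc %*% vapply(basis, function(b) {
      excitedvmc:::.basis_eval(b, r)$v
    }, numeric(1)))
  }, numeric(2))
  expect_equal(unname(cbind(d$up, d$down)), bare, tolerance = 1e-14)
})

test_that("dressed orbitals are equivariant and the determinant antisymmetric", {
  wf <- random_sj_ansatz(seed = 6, n_up = 2, n_down = 1, Z = 3)
  x <- c(0.3, -0.2, 0.5, -0.4, 0.6, -0.1, 0.2, 0.1, -0.7)
  xs <- c(x[4:6], x[1:3], x[7:9])   # swap the two up electrons
  d1 <- dressed_orbitals(wf, x)
  d2 <- dressed_orbitals(wf, xs)
  expect_identical(d1$up[, c(2, 1)], unname(d2$up[, 1:2]) * 1)
  expect_identical(d1$down, d2$down)
  e1 <- psi_eval(wf, matrix(x, 1))
  e2 <- psi_eval(wf, matrix(xs, 1))
  expect_identical(e2$sign, -e1$sign)
  expect_identical(e2$logabs, e1$logabs)
})

test_that("log-domain determinant sum matches a direct determinant oracle", {
  # single determinant, no Jastrow/envelope, orthonormal-ish orbitals:
  # value equals the 2x2 determinant computed directly
  sys <- molecular_system(2, c(0, 0, 0), 2, 0)
  basis <- list(basis_function("gauss_s", exponent = 0.5),
                basis_function("gauss_s", exponent = 1.8))
  oc <- matrix(c(1, 0, 0, 1), 2, 2)
  wf <- slater_jastrow_wavefunction(sys, basis, oc,
                                    list(list(up = c(1L, 2L), down = integer(0))),
                                    jastrow = FALSE, backflow = FALSE,
                                    cusp = FALSE)
  conf <- c(0.4, 0.1, -0.3, -0.6, 0.5, 0.2)
  M <- vapply(1:2, function(j) {
    r <- conf[(3 * j - 2):(3 * j)]
    vapply(basis, function(b) excitedvmc:::.basis_eval(b, r)$v, numeric(1))
  }, numeric(2))
  e <- psi_eval(wf, matrix(conf, 1))
  expect_equal(e$sign * exp(e$logabs), det(M), tolerance = 1e-12)
})

test_that("scaling determinant coefficients shifts the log magnitude only", {
  wf <- random_sj_ansatz(seed = 9)
  th <- wf_params(wf)
  dc <- grep("^dc", names(th))
  th2 <- th
  th2[dc] <- 2 * th2[dc]
  conf <- matrix(c(0.3, -0.2, 0.5, -0.4, 0.6, -0.1), 1)
  e1 <- psi_eval(wf, conf)
  e2 <- psi_eval(wf_set_params(wf, th2), conf)
  expect_identical(e2$sign, e1$sign)
  expect_equal(e2$logabs, e1$logabs + log(2), tolerance = 1e-12)
})

test_that("molecular ansatz derivatives match finite differences", {
  wf <- random_sj_ansatz(seed = 12)
  x <- c(0.3, -0.2, 0.5, -0.4, 0.6, -0.1)
  h <- 1e-5
  lp <- function(z) psi_eval(wf, matrix(z, 1))$logabs
  g <- psi_grad(wf, matrix(x, 1))
  l <- psi_lap(wf, matrix(x, 1))
  fd_g <- vapply(1:6, function(k) {
    xp <- x; xp[k] <- xp[k] + h; xm <- x; xm[k] <- xm[k] - h
    (lp(xp) - lp(xm)) / (2 * h)
  }, numeric(1))
  fd_l <- sum(vapply(1:6, function(k) {
    xp <- x; xp[k] <- xp[k] + h; xm <- x; xm[k] <- xm[k] - h
    (lp(xp) + lp(xm) - 2 * lp(x)) / h^2
  }, numeric(1)))
  expect_equal(drop(g), fd_g, tolerance = 1e-6)
  expect_equal(l, fd_l, tolerance = 1e-4)
  th <- wf_params(wf)
  pg <- psi_pgrad(wf, matrix(x, 1))
  set.seed(3)
  for (k in sort(sample(length(th), 15))) {
    t1 <- th; t1[k] <- t1[k] + h
    t2 <- th; t2[k] <- t2[k] - h
    fd <- (psi_eval(wf_set_params(wf, t1), matrix(x, 1))$logabs -
           psi_eval(wf_set_params(wf, t2), matrix(x, 1))$logabs) / (2 * h)
    expect_equal(unname(pg[1, k]), fd, tolerance = 1e-5)
  }
})

test_that("fixed-spin mode freezes determinant coefficients exactly", {
  sys <- molecular_system(2, c(0, 0, 0), 1, 1)
  basis <- list(basis_function("gauss_s", exponent = 0.7),
                basis_function("gauss_s", exponent = 2.0))
  wf <- slater_jastrow_wavefunction(sys, basis, diag(2),
                                    list(list(up = 1L, down = 1L),
                                         list(up = 2L, down = 2L)),
                                    det_coefs = c(0.9, -0.4), width = 4,
                                    trainable = list(dets = FALSE))
  pg <- psi_pgrad(wf, matrix(c(0.3, -0.2, 0.5, -0.4, 0.6, -0.1), 1))
  dc <- grep("^dc", colnames(pg))
  expect_true(all(pg[, dc] == 0))
  expect_false(all(pg == 0))
})

test_that("with backflow disabled the node set equals the bare expansion's", {
  mk <- function(backflow) {
    sys <- molecular_system(3, c(0, 0, 0), 2, 1)
    basis <- list(basis_function("gauss_s", exponent = 0.5),
                  basis_function("gauss_s", exponent = 1.6),
                  basis_function("gauss_pz", exponent = 0.9))
    slater_jastrow_wavefunction(sys, basis, diag(3),
                                list(list(up = c(1L, 2L), down = 1L)),
                                jastrow = !backflow, backflow = backflow,
                                width = 4, seed = 4)
  }
  wf_jastrow <- mk(FALSE)    # symmetric Jastrow, no backflow
  th <- wf_params(wf_jastrow)
  set.seed(11)
  jj <- grep("^j\\.", names(th))
  th[jj] <- th[jj] + 0.3 * rnorm(length(jj))   # nontrivial Jastrow weights
  wf_jastrow <- wf_set_params(wf_jastrow, th)
  wf_bare <- slater_jastrow_wavefunction(
    molecular_system(3, c(0, 0, 0), 2, 1),
    list(basis_function("gauss_s", exponent = 0.5),
         basis_function("gauss_s", exponent = 1.6),
         basis_function("gauss_pz", exponent = 0.9)),
    diag(3), list(list(up = c(1L, 2L), down = 1L)),
    jastrow = FALSE, backflow = FALSE, cusp = FALSE
  )
  set.seed(10)
  X <- matrix(rnorm(9 * 200), ncol = 9)
  expect_identical(psi_eval(wf_jastrow, X)$sign, psi_eval(wf_bare, X)$sign)
})
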