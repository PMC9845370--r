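# Ground-truth machinery: dense-grid eigensolvers for low-dimensional
# systems, quadrature matrix elements, and the exact two-state mixture
# fixture used to calibrate every estimator.

#' Dense-grid eigensolver for low-dimensional systems
#'
#' Second-order central finite differences on a uniform grid, diagonalized
#' for the lowest `n_states` eigenpairs. Supported: 1D one-particle model
#' systems (harmonic, box, soft Coulomb), the s-wave radial channel of a
#' hydrogenic atom (one nucleus, one electron), and interacting 1D
#' two-particle model systems on the tensor-product grid with exchange
#' symmetry selected by `symmetry`.
#'
#' Refuses (with diagnostics) if an eigenfunction puts more than `1e-6` of
#' its mass on the boundary nodes, which signals insufficient extent.
#'
#' @param system a `vmc_system`.
#' @param n_states number of eigenpairs.
#' @param n number of grid nodes per dimension.
#' @param extent half-width of the grid (model systems) or maximum radius
#'   (radial); chosen automatically if `NULL`.
#' @param symmetry for two-particle grids: `"any"`, `"symmetric"` or
#'   `"antisymmetric"` exchange sector.
#' @return object of class `grid_solution`: `energies`, `states` (columns,
#'   quadrature-orthonormal), `grid`, `spacing`, `weights`.
#' @export
grid_eigensolve <- function(system, n_states, n = 801L, extent = NULL,
                            symmetry = c("any", "symmetric", "antisymmetric")) {
  symmetry <- match.arg(symmetry)
  if (inherits(system, "molecular_system")) {
    stopifnot(nrow(system$positions) == 1, n_particles(system) == 1)
    return(.grid_radial(system$charges[1], n_states, n,
                        extent = extent %||% 60))
  }
  stopifnot(system$d == 1L)
  if (system$n_particles == 1L) {
    .grid_1d(system, n_states, n, extent)
  } else if (system$n_particles == 2L) {
    .grid_2p(system, n_states, n, extent, symmetry)
  } else {
    stop("grid_eigensolve supports at most two particles")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.grid_axis <- function(system, n, extent) {
  if (system$potential == "box") {
    L <- system$box_length
    h <- L / (n + 1)
    seq(h, L - h, length.out = n)   # Dirichlet walls at 0 and L
  } else {
    ext <- extent %||% switch(system$potential,
      harmonic = 9 / sqrt(system$omega),
      soft_coulomb = 25
    )
    seq(-ext, ext, length.out = n)
  }
}

.check_boundary_mass <- function(states, weights, tol = 1e-6,
                                 edge = c(1L, nrow(states))) {
  mass <- apply(states, 2, function(v) {
    sum(weights[edge] * v[edge]^2) / sum(weights * v^2)
  })
  if (any(mass > tol)) {
    stop(sprintf(
      "grid_eigensolve: eigenfunction boundary mass %.2e exceeds %.0e; increase the grid extent",
      max(mass), tol
    ))
  }
}

.fd_hamiltonian <- function(x, V) {
  n <- length(x)
  h <- x[2] - x[1]
  H <- diag(V + 1 / h^2)
  off <- -0.5 / h^2
  H[cbind(seq_len(n - 1), 2:n)] <- off
  H[cbind(2:n, seq_len(n - 1))] <- off
  H
}

.grid_1d <- function(system, n_states, n, extent, refine = TRUE) {
  x <- .grid_axis(system, n, extent)
  h <- x[2] - x[1]
  V <- potential_energy(system, matrix(x, ncol = 1), check = FALSE)
  eg <- eigen(.fd_hamiltonian(x, V), symmetric = TRUE)
  ord <- order(eg$values)[seq_len(n_states)]
  energies <- eg$values[ord]
  if (refine && n >= 101L) {
    # Richardson step: the second-order scheme has O(h^2) eigenvalue error,
    # so combining two spacings at fixed extent gives O(h^4)
    n2 <- (n + 1L) %/% 2L
    x2 <- .grid_axis(system, n2, extent)
    V2 <- potential_energy(system, matrix(x2, ncol = 1), check = FALSE)
    eg2 <- eigen(.fd_hamiltonian(x2, V2), symmetric = TRUE)
    e2 <- sort(eg2$values)[seq_len(n_states)]
    r <- (h / (x2[2] - x2[1]))^2
    energies <- (energies - r * e2) / (1 - r)
  }
  states <- eg$vectors[, ord, drop = FALSE] / sqrt(h)
  w <- rep(h, n)
  if (system$potential != "box") .check_boundary_mass(states, w)
  # fix a reproducible overall sign: positive at the peak-magnitude node
  for (k in seq_len(ncol(states))) {
    pk <- which.max(abs(states[, k]))
    if (states[pk, k] < 0) states[, k] <- -states[, k]
  }
  structure(
    list(energies = energies, states = states, grid = x,
         spacing = h, weights = w, kind = "1d"),
    class = "grid_solution"
  )
}

.grid_radial <- function(Z, n_states, n, extent) {
  r <- seq(extent / n, extent, length.out = n)
  h <- r[2] - r[1]
  eg <- eigen(.fd_hamiltonian(r, -Z / r), symmetric = TRUE)
  ord <- order(eg$values)[seq_len(n_states)]
  states <- eg$vectors[, ord, drop = FALSE] / sqrt(h)
  .check_boundary_mass(states, rep(h, n), edge = n)  # u(0) = 0 is physical
  structure(
    list(energies = eg$values[ord], states = states, grid = r,
         spacing = h, weights = rep(h, n), kind = "radial"),
    class = "grid_solution"
  )
}

.grid_2p <- function(system, n_states, n, extent, symmetry) {
  n <- min(n, 61L)   # dense tensor-product diagonalization
  x <- .grid_axis(system, n, extent)
  h <- x[2] - x[1]
  one <- model_system(system$potential, d = 1, n_particles = 1,
                      omega = system$omega, box_length = system$box_length,
                      soft = system$soft)
  v1 <- potential_energy(one, matrix(x, ncol = 1), check = FALSE)
  H1 <- .fd_hamiltonian(x, v1)
  Id <- diag(n)
  H <- kronecker(H1, Id) + kronecker(Id, H1)
  if (system$interaction) {
    X1 <- rep(x, times = n); X2 <- rep(x, each = n)
    H <- H + diag(1 / sqrt((X1 - X2)^2 + system$soft^2))
  }
  eg <- eigen(H, symmetric = TRUE)
  ord <- order(eg$values)
  # exchange operator permutes the tensor indices
  perm <- as.vector(matrix(seq_len(n^2), n, n, byrow = TRUE))
  keep <- integer(0)
  for (k in ord) {
    v <- eg$vectors[, k]
    sym <- sum(v * v[perm])   # +1 symmetric, -1 antisymmetric
    ok <- switch(symmetry,
      any = TRUE,
      symmetric = sym > 0.5,
      antisymmetric = sym < -0.5
    )
    if (ok) keep <- c(keep, k)
    if (length(keep) >= n_states) break
  }
  if (length(keep) < n_states) stop("grid_eigensolve: not enough states in the requested symmetry sector")
  states <- eg$vectors[, keep, drop = FALSE] / h
  structure(
    list(energies = eg$values[keep], states = states,
         grid = x, spacing = h, weights = rep(h^2, n^2), kind = "2p"),
    class = "grid_solution"
  )
}

#' @export
print.grid_solution <- function(x, ...) {
  cat(sprintf("<grid_solution (%s): %d state(s), E = %s>\n", x$kind,
              length(x$energies),
              paste(sprintf("%.6f", x$energies), collapse = ", ")))
  invisible(x)
}

#' Wrap a grid eigenfunction as a wavefunction (1D)
#' @param sol a `grid_solution` of kind `"1d"`.
#' @param k state index (1-based).
#' @export
grid_state_wavefunction <- function(sol, k) {
  stopifnot(sol$kind == "1d")
  grid_wavefunction(sol$grid, sol$states[, k])
}

#' Two-state mixture fixture
#'
#' `psi_eps = sqrt(1 - eps) psi_1 + sqrt(eps) psi_0` for orthonormal states
#' `psi_0`, `psi_1`. The exact overlap with `psi_0` is `sqrt(eps)` and the
#' exact energy is `(1 - eps) E_1 + eps E_0`, which calibrates the overlap
#' and energy estimators. Orthonormality is verified by quadrature and
#' non-conforming inputs are rejected.
#'
#' @param eps mixing weight in `[0, 1]`.
#' @param wf0,wf1 orthonormal wavefunctions (1D).
#' @param grid quadrature nodes for the orthonormality check.
#' @param tol quadrature tolerance.
#' @return object of class `mixture_fixture`: the mixed state `wf`, the
#'   components, `eps` and the exact `overlap0 = sqrt(eps)`.
#' @export
make_mixture <- function(eps, wf0, wf1, grid = seq(-12, 12, length.out = 4001),
                         tol = 1e-6) {
  stopifnot(eps >= 0, eps <= 1)
  n0 <- quadrature_observable(op_identity(), wf0, wf0, grid, normalize = FALSE)
  n1 <- quadrature_observable(op_identity(), wf1, wf1, grid, normalize = FALSE)
  s01 <- quadrature_observable(op_identity(), wf0, wf1, grid, normalize = FALSE)
  if (abs(n0 - 1) > tol || abs(n1 - 1) > tol || abs(s01) > tol) {
    stop(sprintf(
      "make_mixture: states not orthonormal under quadrature (|n0-1|=%.1e, |n1-1|=%.1e, |s01|=%.1e)",
      abs(n0 - 1), abs(n1 - 1), abs(s01)
    ))
  }
  structure(
    list(eps = eps, wf0 = wf0, wf1 = wf1,
         wf = linear_combo_wavefunction(c(sqrt(1 - eps), sqrt(eps)),
                                        list(wf1, wf0)),
         overlap0 = sqrt(eps)),
    class = "mixture_fixture"
  )
}

#' Exact matrix element by grid quadrature
#'
#' Riemann-sum evaluation of `<psi_A | O | psi_B>` on a common 1D grid,
#' normalized by the quadrature norms of both states by default — the truth
#' value that Monte Carlo mixed estimates are tested against.
#'
#' @param op a `local_operator`.
#' @param wf_a,wf_b wavefunctions on the same 1D configuration space.
#' @param grid quadrature nodes (uniform), or a list with `nodes` and
#'   `weights`.
#' @param normalize divide by the state norms?
#' @return the matrix element (numeric scalar).
#' @export
quadrature_observable <- function(op, wf_a, wf_b, grid, normalize = TRUE) {
  if (is.list(grid)) {
    x <- grid$nodes; w <- grid$weights
  } else {
    x <- grid; w <- rep(x[2] - x[1], length(x))
  }
  X <- matrix(x, ncol = 1)
  ea <- psi_eval(wf_a, X); eb <- psi_eval(wf_b, X)
  va <- ea$sign * exp(ea$logabs)
  vb <- eb$sign * exp(eb$logabs)
  act <- op$apply(wf_b, X)
  act[!is.finite(act)] <- 0   # nodes of psi_b contribute zero measure
  val <- sum(w * va * vb * act)
  if (normalize) {
    val <- val / sqrt(sum(w * va^2) * sum(w * vb^2))
  }
  val
}

#' Quadrature grid as a weighted batch
#'
#' Packages 1D grid nodes as a `config_batch` whose base density equals the
#' quadrature weight, so Monte Carlo estimators evaluate exact (quadrature)
#' expectations. Used as the "frozen common points" in gradient
#' finite-difference validations.
#'
#' @param x grid nodes (uniform spacing).
#' @export
quadrature_batch <- function(x) {
  h <- x[2] - x[1]
  config_batch(matrix(x, ncol = 1), log_base = rep(-log(h), length(x)))
}
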