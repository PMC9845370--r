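# Hamiltonians: molecular Coulomb systems and analytic model potentials, plus
# the local-energy functional that every trial wavefunction is scored by.
#
# Conventions: Hartree atomic units throughout; electron configurations are
# stored as matrices with one walker per row and N*d columns, electron i
# occupying columns ((i-1)*d+1):(i*d); the first n_up electrons are spin-up.

BOHR_PER_ANGSTROM <- 1.8897259886

#' Molecular Coulomb system
#'
#' Defines the Born-Oppenheimer Hamiltonian of a molecule: point nuclei with
#' charges `charges` at `positions` (bohr) and `n_up` + `n_down` electrons.
#'
#' @param charges positive integer nuclear charges Z.
#' @param positions numeric matrix (n_nuclei x 3) of nuclear coordinates in
#'   bohr, or a length-3 vector for a single nucleus.
#' @param n_up,n_down electron counts per spin channel (`n_up >= n_down >= 0`).
#' @return an object of class `c("molecular_system", "vmc_system")`.
#' @examples
#' hydrogen <- molecular_system(1, c(0, 0, 0), n_up = 1, n_down = 0)
#' @export
molecular_system <- function(charges, positions, n_up, n_down) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1)
  positions <- as.matrix(positions)
  stopifnot(
    ncol(positions) == 3, nrow(positions) == length(charges),
    all(charges >= 1), all(is.finite(positions)),
    n_up >= n_down, n_down >= 0, n_up + n_down >= 1
  )
  structure(
    list(
      charges = as.numeric(charges), positions = positions,
      n_up = as.integer(n_up), n_down = as.integer(n_down),
      d = 3L
    ),
    class = c("molecular_system", "vmc_system")
  )
}

#' Analytic model system
#'
#' Low-dimensional model Hamiltonians with closed-form or grid-computable
#' spectra, used as desk-scale references: the harmonic trap
#' `V = omega^2 x^2 / 2`, the infinite box of length `L` (V = 0 inside
#' `[0, L]`), and the (soft-)Coulomb centre `V = -1/sqrt(x^2 + soft^2)`.
#' Particles may interact pairwise through a soft Coulomb repulsion.
#'
#' @param potential one of `"harmonic"`, `"box"`, `"soft_coulomb"`.
#' @param d dimensionality (1-3).
#' @param n_particles particle count.
#' @param n_up number of spin-up particles (defaults to all).
#' @param omega harmonic angular frequency (> 0).
#' @param box_length box length L (> 0).
#' @param soft softening parameter of the Coulomb terms (>= 0; 0 means bare).
#' @param interaction logical; include pairwise `1/sqrt(r^2 + soft^2)`?
#' @return an object of class `c("model_system", "vmc_system")`.
#' @examples
#' trap <- model_system("harmonic", omega = 1)
#' @export
model_system <- function(potential = c("harmonic", "box", "soft_coulomb"),
                         d = 1L, n_particles = 1L, n_up = n_particles,
                         omega = 1, box_length = 1, soft = 1,
                         interaction = FALSE) {
  potential <- match.arg(potential)
  stopifnot(d >= 1, d <= 3, n_particles >= 1, n_up >= 0, n_up <= n_particles)
  if (potential == "harmonic") stopifnot(omega > 0)
  if (potential == "box") stopifnot(box_length > 0)
  stopifnot(soft >= 0)
  structure(
    list(
      potential = potential, d = as.integer(d),
      n_particles = as.integer(n_particles),
      n_up = as.integer(n_up), n_down = as.integer(n_particles - n_up),
      omega = omega, box_length = box_length, soft = soft,
      interaction = isTRUE(interaction)
    ),
    class = c("model_system", "vmc_system")
  )
}

#' Number of particles of a system
#' @param system a `vmc_system`.
#' @export
n_particles <- function(system) UseMethod("n_particles")

#' @export
n_particles.molecular_system <- function(system) system$n_up + system$n_down

#' @export
n_particles.model_system <- function(system) system$n_particles

#' Dimensionality of a system
#' @param system a `vmc_system`.
#' @export
system_dim <- function(system) system$d

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf(
    "<molecular_system: %d nuclei (sum Z = %g), %d up + %d down electrons>\n",
    nrow(x$positions), sum(x$charges), x$n_up, x$n_down
  ))
  invisible(x)
}

#' @export
print.model_system <- function(x, ...) {
  cat(sprintf(
    "<model_system: %s, d = %d, %d particle(s)%s>\n",
    x$potential, x$d, x$n_particles,
    if (x$interaction) ", interacting" else ""
  ))
  invisible(x)
}

as_conf_matrix <- function(conf, system) {
  nd <- n_particles(system) * system$d
  if (is.null(dim(conf))) conf <- matrix(conf, ncol = nd, byrow = TRUE)
  if (ncol(conf) != nd) {
    stop(sprintf("configuration has %d coordinates, system needs %d",
                 ncol(conf), nd))
  }
  conf
}

particle_block <- function(i, d) ((i - 1L) * d + 1L):(i * d)

# squared distances between particle i rows of X and a fixed point p (len d)
.dist_to_point <- function(X, i, d, p) {
  cols <- particle_block(i, d)
  D2 <- 0
  for (k in seq_len(d)) D2 <- D2 + (X[, cols[k]] - p[k])^2
  sqrt(D2)
}

.dist_between <- function(X, i, j, d) {
  ci <- particle_block(i, d); cj <- particle_block(j, d)
  D2 <- 0
  for (k in seq_len(d)) D2 <- D2 + (X[, ci[k]] - X[, cj[k]])^2
  sqrt(D2)
}

#' Potential energy of electron configurations
#'
#' For molecular systems the full Coulomb potential
#' `sum_{i<j} 1/r_ij - sum_{i,I} Z_I/r_iI + sum_{I<J} Z_I Z_J / R_IJ`
#' (nuclear repulsion included, so energies are totals); for model systems
#' the configured analytic potential. Vectorized over walkers (rows).
#'
#' @param system a `vmc_system`.
#' @param conf configuration matrix (walkers x N*d) or a single flat vector.
#' @param check if `TRUE` (default), a coincident electron-nucleus or
#'   electron-electron pair signals a `singular_configuration` condition.
#' @return numeric vector of potential energies (Ha), one per walker.
#' @export
potential_energy <- function(system, conf, check = TRUE) {
  UseMethod("potential_energy")
}

#' @export
potential_energy.molecular_system <- function(system, conf, check = TRUE) {
  X <- as_conf_matrix(conf, system)
  N <- n_particles(system)
  V <- numeric(nrow(X))
  for (i in seq_len(N)) {
    for (I in seq_along(system$charges)) {
      r <- .dist_to_point(X, i, 3L, system$positions[I, ])
      if (check && any(r == 0)) stop(singular_configuration(X[r == 0, , drop = FALSE]))
      V <- V - system$charges[I] / r
    }
  }
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        r <- .dist_between(X, i, j, 3L)
        if (check && any(r == 0)) stop(singular_configuration(X[r == 0, , drop = FALSE]))
        V <- V + 1 / r
      }
    }
  }
  M <- nrow(system$positions)
  if (M > 1) {
    for (I in seq_len(M - 1)) {
      for (J in (I + 1):M) {
        RIJ <- sqrt(sum((system$positions[I, ] - system$positions[J, ])^2))
        V <- V + system$charges[I] * system$charges[J] / RIJ
      }
    }
  }
  V
}

#' @export
potential_energy.model_system <- function(system, conf, check = TRUE) {
  X <- as_conf_matrix(conf, system)
  N <- system$n_particles
  d <- system$d
  V <- numeric(nrow(X))
  for (i in seq_len(N)) {
    cols <- particle_block(i, d)
    r2 <- rowSums(X[, cols, drop = FALSE]^2)
    V <- V + switch(system$potential,
      harmonic = 0.5 * system$omega^2 * r2,
      box = {
        inside <- apply(X[, cols, drop = FALSE], 1, function(x) {
          all(x >= 0 & x <= system$box_length)
        })
        ifelse(inside, 0, Inf)
      },
      soft_coulomb = {
        r <- sqrt(r2 + system$soft^2)
        if (check && any(r == 0)) stop(singular_configuration(X[r == 0, , drop = FALSE]))
        -1 / r
      }
    )
  }
  if (system$interaction && N > 1) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        r <- .dist_between(X, i, j, d)
        rr <- sqrt(r^2 + system$soft^2)
        if (check && any(rr == 0)) stop(singular_configuration(X[rr == 0, , drop = FALSE]))
        V <- V + 1 / rr
      }
    }
  }
  V
}

#' Local energy of a trial wavefunction
#'
#' `E_loc(r) = H psi(r) / psi(r)`, evaluated in the log domain as
#' `-1/2 * (lap ln|psi| + |grad ln|psi||^2) + V(r)` with exact analytic
#' derivatives supplied by the wavefunction object (never finite
#' differences). Constant over configuration space exactly when `psi` is an
#' eigenstate (zero-variance principle).
#'
#' @param wf a wavefunction object (see [psi_eval()]).
#' @param system a `vmc_system`.
#' @param conf configuration matrix (walkers x N*d) or flat vector.
#' @param check signal conditions on singular / non-finite input?
#' @return numeric vector of local energies (Ha), one per walker.
#' @export
local_energy <- function(wf, system, conf, check = TRUE) {
  X <- as_conf_matrix(conf, system)
  g <- psi_grad(wf, X)
  l <- psi_lap(wf, X)
  if (check && any(!is.finite(g)) || check && any(!is.finite(l))) {
    bad <- !is.finite(l) | rowSums(!is.finite(g)) > 0
    stop(numerical_breakdown(X[bad, , drop = FALSE]))
  }
  kin <- -0.5 * (l + rowSums(g * g))
  kin + potential_energy(system, X, check = check)
}
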