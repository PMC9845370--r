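# State initialization: analytic providers for solvable systems and an
# engine-agnostic adapter for externally computed multi-determinant
# baselines (state-averaged CASSCF products), plus determinant truncation.

#' Analytic baseline states for solvable systems
#'
#' Builds the lowest `n_states` exact (or grid-computed) states of a
#' solvable system and wraps each in a trainable ansatz of the matching
#' family, initialized exactly at the baseline (mutually orthogonal by
#' construction). An optional Gaussian perturbation of relative size
#' `perturb` makes the starting point approximate, emulating an inexact
#' quantum-chemistry baseline.
#'
#' Supported: 1D harmonic model systems (polynomial-Gaussian family),
#' 1D box (frozen eigenstates), hydrogenic atoms (radial family; 1s, 2s,
#' then 2p_z).
#'
#' @param system a `vmc_system`.
#' @param n_states number of states.
#' @param provider `"closed_form"` or `"grid"` (grid eigensolver; model
#'   systems only, returns frozen spline states).
#' @param degree polynomial degree of the trainable families.
#' @param perturb relative perturbation scale (0 = exact baseline).
#' @param seed seed for the perturbation.
#' @return object of class `baseline_solution`: trainable `states`, frozen
#'   `orbitals`, exact `energies`, `n_states`.
#' @export
analytic_baseline <- function(system, n_states, provider = c("closed_form", "grid"),
                              degree = NULL, perturb = 0, seed = 1L) {
  provider <- match.arg(provider)
  stopifnot(n_states >= 1)
  if (provider == "grid") {
    sol <- grid_eigensolve(system, n_states, n = 1601L)
    if (sol$kind != "1d") stop("grid provider supports 1D one-particle systems")
    states <- lapply(seq_len(n_states), function(k) grid_state_wavefunction(sol, k))
    return(structure(
      list(states = states, orbitals = states, energies = sol$energies,
           n_states = n_states, det_lists = .unit_dets(n_states)),
      class = "baseline_solution"
    ))
  }
  if (inherits(system, "molecular_system")) {
    if (nrow(system$positions) != 1 || n_particles(system) != 1) {
      stop("analytic baselines exist for hydrogenic atoms only; use import_casscf for molecules")
    }
    Z <- system$charges[1]
    labels <- c("1s", "2s", "2pz")
    if (n_states > length(labels)) {
      stop(sprintf("requested %d states; %d analytic hydrogenic states available",
                   n_states, length(labels)))
    }
    K <- degree %||% 2L
    orbitals <- lapply(labels[seq_len(n_states)], hydrogenic_state, Z = Z)
    states <- lapply(seq_len(n_states), function(k) {
      frozen <- orbitals[[k]]
      coef <- numeric(K + 1L)
      base_coef <- wf_params(frozen)[seq_len(frozen$K + 1L)]
      coef[seq_along(base_coef)] <- base_coef
      radial_poly_wavefunction(coef, alpha = exp(wf_params(frozen)[["log_alpha"]]),
                               angular = frozen$angular)
    })
    energies <- c(-Z^2 / 2, -Z^2 / 8, -Z^2 / 8)[seq_len(n_states)]
  } else if (system$potential == "harmonic" && system$d == 1L &&
             system$n_particles == 1L) {
    K <- degree %||% max(3L, n_states + 2L)
    orbitals <- lapply(seq_len(n_states) - 1L, harmonic_eigenstate,
                       omega = system$omega)
    states <- lapply(seq_len(n_states), function(k) {
      frozen <- orbitals[[k]]
      coef <- numeric(K + 1L)
      coef[seq_len(k)] <- wf_params(frozen)[seq_len(k)]
      poly_gauss_wavefunction(coef, a = system$omega, b = 0)
    })
    energies <- (seq_len(n_states) - 0.5) * system$omega
  } else if (system$potential == "box" && system$d == 1L &&
             system$n_particles == 1L) {
    orbitals <- lapply(seq_len(n_states), box_eigenstate, L = system$box_length)
    states <- orbitals
    energies <- (seq_len(n_states) * pi / system$box_length)^2 / 2
  } else {
    stop("no analytic baseline for this system; use the grid provider")
  }
  if (perturb > 0) {
    res <- with_rng_state(NULL, {
      set.seed(derive_seed(seed, 99L))
      lapply(states, function(wf) {
        th <- wf_params(wf)
        if (!length(th)) return(wf)
        scale <- max(abs(th))
        wf_set_params(wf, th + perturb * scale * stats::rnorm(length(th)))
      })
    })
    states <- res$value
  }
  structure(
    list(states = states, orbitals = orbitals, energies = energies,
         n_states = n_states, det_lists = .unit_dets(n_states)),
    class = "baseline_solution"
  )
}

.unit_dets <- function(n_states) {
  lapply(seq_len(n_states), function(k) {
    data.frame(det = k, coef = 1)
  })
}

#' @export
print.baseline_solution <- function(x, ...) {
  cat(sprintf("<baseline_solution: %d state(s), E = %s>\n", x$n_states,
              paste(sprintf("%.4f", x$energies), collapse = ", ")))
  invisible(x)
}

# analytic overlap of two cartesian-Gaussian basis functions (s or p)
.gauss_overlap <- function(bf1, bf2) {
  stopifnot(grepl("^gauss", bf1$type), grepl("^gauss", bf2$type))
  a <- bf1$exponent; b <- bf2$exponent
  p <- a + b
  ax1 <- switch(bf1$type, gauss_px = 1L, gauss_py = 2L, gauss_pz = 3L, 0L)
  ax2 <- switch(bf2$type, gauss_px = 1L, gauss_py = 2L, gauss_pz = 3L, 0L)
  out <- 1
  for (al in 1:3) {
    X <- bf1$center[al] - bf2$center[al]
    s00 <- sqrt(pi / p) * exp(-a * b * X^2 / p)
    l1 <- as.integer(ax1 == al); l2 <- as.integer(ax2 == al)
    out <- out * if (l1 == 0 && l2 == 0) {
      s00
    } else if (l1 == 1 && l2 == 0) {
      -b * X / p * s00
    } else if (l1 == 0 && l2 == 1) {
      a * X / p * s00
    } else {
      s00 * (-a * b * X^2 / p^2 + 1 / (2 * p))
    }
  }
  out
}

#' Import an externally computed multi-determinant baseline
#'
#' Engine-agnostic adapter for state-averaged multi-configuration products:
#' molecular-orbital coefficients over a Gaussian basis, per-state CI
#' determinant lists with coefficients, and active-space metadata. Builds
#' one trainable Slater-Jastrow-backflow ansatz per state (zero-initialized
#' networks, so the fresh ansatz is exactly the imported baseline with the
#' cusp envelope attached). Orbitals are checked for orthonormality under
#' the analytic Gaussian overlap and rejected beyond `ortho_tol`.
#'
#' @param payload list with elements `basis` (list of lists with `type`,
#'   `center`, `exponent` — see [basis_function()]), `mo_coeffs` (matrix
#'   n_orbitals x n_basis), `states` (per state: `dets`, a list of
#'   `list(up=, down=)` occupations, and `coefs`), and optionally
#'   `active_space` metadata. May also be a path to a JSON file with the
#'   same structure.
#' @param system a `molecular_system`.
#' @param n_states number of states to build.
#' @param max_dets determinant budget per state (truncation by largest
#'   `|c_p|`).
#' @param ortho_tol orbital orthonormality tolerance.
#' @param ... passed to [slater_jastrow_wavefunction()] (networks, widths,
#'   trainable flags).
#' @return a `baseline_solution` whose `states` are molecular ansatzes.
#' @export
import_casscf <- function(payload, system, n_states, max_dets = 10L,
                          ortho_tol = 1e-6, ...) {
  if (is.character(payload)) {
    payload <- jsonlite::read_json(payload, simplifyVector = TRUE)
  }
  basis <- lapply(seq_along(payload$basis$type %||% payload$basis), function(k) {
    b <- if (is.data.frame(payload$basis)) as.list(payload$basis[k, ]) else payload$basis[[k]]
    basis_function(b$type, unlist(b$center), b$exponent)
  })
  mo <- as.matrix(payload$mo_coeffs)
  if (is.data.frame(payload$states)) {
    payload$states <- lapply(seq_len(nrow(payload$states)), function(r) {
      list(dets = payload$states$dets[[r]], coefs = payload$states$coefs[[r]])
    })
  }
  if (length(payload$states) < n_states) {
    stop(sprintf("payload supplies %d state(s); %d requested",
                 length(payload$states), n_states))
  }
  # orthonormality of the orbitals under the analytic Gaussian overlap
  nb <- length(basis)
  Sb <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    Sb[i, j] <- .gauss_overlap(basis[[i]], basis[[j]])
  }
  Smo <- mo %*% Sb %*% t(mo)
  dev <- max(abs(Smo - diag(nrow(mo))))
  if (dev > ortho_tol) {
    stop(sprintf("import_casscf: orbitals deviate from orthonormality by %.2e (tol %.0e)",
                 dev, ortho_tol))
  }
  normalize_dets <- function(dets) {
    if (is.data.frame(dets)) {
      dets <- lapply(seq_len(nrow(dets)), function(r) {
        list(up = dets$up[[r]], down = dets$down[[r]])
      })
    }
    lapply(dets, function(d) list(up = as.integer(unlist(d[["up"]])),
                                  down = as.integer(unlist(d[["down"]]))))
  }
  states <- lapply(seq_len(n_states), function(st) {
    spec <- payload$states[[st]]
    coefs <- as.numeric(spec$coefs)
    spec$dets <- normalize_dets(spec$dets)
    keep <- select_determinants(list(coefs), max_dets)[[1]]
    dets <- spec$dets[keep$index]
    slater_jastrow_wavefunction(system, basis, mo, dets,
                                det_coefs = keep$coefs, ...)
  })
  structure(
    list(states = states, orbitals = list(basis = basis, mo_coeffs = mo),
         energies = rep(NA_real_, n_states), n_states = n_states,
         det_lists = lapply(seq_len(n_states), function(st) {
           keep <- select_determinants(list(as.numeric(payload$states[[st]]$coefs)),
                                       max_dets)[[1]]
           data.frame(det = keep$index, coef = keep$coefs)
         }),
         active_space = payload$active_space),
    class = "baseline_solution"
  )
}

#' Truncate determinant expansions by coefficient magnitude
#'
#' Keeps, per state, the `max_dets` determinants of largest `|c_p|`
#' (descending, ties broken by original index), renormalizing the retained
#' coefficients to unit norm.
#'
#' @param coef_list list of per-state coefficient vectors.
#' @param max_dets determinant budget (>= 1).
#' @return list of per-state lists with `index` (original positions, kept
#'   order) and `coefs` (renormalized).
#' @export
select_determinants <- function(coef_list, max_dets) {
  stopifnot(max_dets >= 1)
  lapply(coef_list, function(cf) {
    ord <- order(-abs(cf), seq_along(cf))
    keep <- ord[seq_len(min(max_dets, length(cf)))]
    kept <- cf[keep]
    list(index = keep, coefs = kept / sqrt(sum(kept^2)))
  })
}
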