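# Metropolis-adjusted Langevin sampling of |psi|^2. Each state owns one
# ensemble of walkers with its own RNG stream; the Metropolis correction
# makes the stationary law exact, which the estimator validations rely on.

#' Initialize a walker ensemble
#'
#' Walkers are placed by perturbing the nuclear positions (molecular
#' systems) or the potential minimum (model systems) with unit Gaussian
#' noise, then burned in. Deterministic given `seed`; each ensemble carries
#' an independent RNG stream.
#'
#' @param wf wavefunction to sample (`|psi|^2` target).
#' @param system a `vmc_system`.
#' @param B number of walkers (>= 1).
#' @param seed integer seed for this chain's RNG stream.
#' @param burn number of burn-in steps.
#' @param step initial Langevin step size `delta`.
#' @return an object of class `walker_ensemble`.
#' @export
init_walkers <- function(wf, system, B, seed, burn = 200L, step = 0.3) {
  stopifnot(B >= 1, step > 0)
  N <- n_particles(system)
  d <- system_dim(system)
  res <- with_rng_state(NULL, {
    set.seed(derive_seed(seed, 0L))
    X <- matrix(0, B, N * d)
    for (i in seq_len(N)) {
      cols <- particle_block(i, d)
      if (!inherits(system, "molecular_system") && system$potential == "box") {
        # support is bounded: draw uniformly inside the box
        X[, cols] <- matrix(stats::runif(B * d, 0, system$box_length), B, d)
        next
      }
      center <- if (inherits(system, "molecular_system")) {
        system$positions[1L + (i - 1L) %% nrow(system$positions), ]
      } else {
        rep(0, d)
      }
      X[, cols] <- matrix(rep(center, each = B), B, d) +
        matrix(stats::rnorm(B * d), B, d)
    }
    X
  })
  X <- res$value
  e <- psi_eval(wf, X)
  # walkers that landed exactly on nodes get re-jittered
  tries <- 0L
  while (any(e$sign == 0) && tries < 20L) {
    bad <- which(e$sign == 0)
    r2 <- with_rng_state(res$state, {
      X[bad, ] <- X[bad, , drop = FALSE] +
        0.1 * matrix(stats::rnorm(length(bad) * ncol(X)), length(bad))
      X
    })
    X <- r2$value; res$state <- r2$state
    e <- psi_eval(wf, X)
    tries <- tries + 1L
  }
  if (any(e$sign == 0)) {
    stop("init_walkers: could not move initial walkers off the nodal set")
  }
  ens <- structure(
    list(X = X, sign = e$sign, logabs = e$logabs, step = step,
         n_moves = 0L, n_accept = 0L, acc_rate = NA_real_,
         tuning_frozen = FALSE, n_reinit = 0L, rng = res$state,
         global_scale = 2 * pmax(apply(X, 2, stats::sd), 0.5)),
    class = "walker_ensemble"
  )
  if (burn > 0L) {
    ens <- run_chain(ens, wf, system, steps = burn, tune_every = 50L)
  }
  ens
}

#' @export
print.walker_ensemble <- function(x, ...) {
  cat(sprintf("<walker_ensemble: %d walkers, step %.3g, acceptance %.3f>\n",
              nrow(x$X), x$step, ifelse(is.na(x$acc_rate), NaN, x$acc_rate)))
  invisible(x)
}

#' One Metropolis-adjusted Langevin move per walker
#'
#' Proposes `x' = x + delta^2 * grad ln|psi|(x) + delta * xi` (the drift is
#' `delta^2/2 * grad ln|psi|^2`) and accepts with the Metropolis-Hastings
#' ratio for the drifted Gaussian proposal. Proposals on nodes (sign 0) are
#' auto-rejected; walkers with non-finite drift are re-initialized near
#' their old position and counted in `n_reinit`.
#'
#' @param ensemble a `walker_ensemble`.
#' @param wf the current wavefunction.
#' @param system a `vmc_system`.
#' @return the updated ensemble.
#' @export
langevin_step <- function(ensemble, wf, system) {
  X <- ensemble$X
  B <- nrow(X); nd <- ncol(X)
  delta <- ensemble$step
  gX <- psi_grad(wf, X)
  bad <- rowSums(!is.finite(gX)) > 0
  if (any(bad)) {
    ensemble$n_reinit <- ensemble$n_reinit + sum(bad)
    r <- with_rng_state(ensemble$rng, {
      X[bad, ] <- X[bad, , drop = FALSE] +
        0.5 * matrix(stats::rnorm(sum(bad) * nd), sum(bad))
      X
    })
    X <- r$value; ensemble$rng <- r$state
    gX <- psi_grad(wf, X)
    gX[!is.finite(gX)] <- 0
    e <- psi_eval(wf, X)
    ensemble$sign <- e$sign; ensemble$logabs <- e$logabs
  }
  r <- with_rng_state(ensemble$rng, {
    matrix(stats::rnorm(B * nd), B, nd)
  })
  xi <- r$value; ensemble$rng <- r$state
  Y <- X + delta^2 * gX + delta * xi
  eY <- psi_eval(wf, Y)
  gY <- psi_grad(wf, Y)
  gY[!is.finite(gY)] <- 0
  # log q(x | y) - log q(y | x) for the drifted Gaussian proposal
  fwd <- Y - X - delta^2 * gX
  bwd <- X - Y - delta^2 * gY
  log_q <- (rowSums(fwd^2) - rowSums(bwd^2)) / (2 * delta^2)
  log_alpha <- 2 * (eY$logabs - ensemble$logabs) + log_q
  log_alpha[eY$sign == 0 | !is.finite(eY$logabs)] <- -Inf
  r <- with_rng_state(ensemble$rng, stats::runif(B))
  u <- r$value; ensemble$rng <- r$state
  accept <- log(u) < log_alpha
  if (any(accept)) {
    ensemble$X[accept, ] <- Y[accept, , drop = FALSE]
    ensemble$logabs[accept] <- eY$logabs[accept]
    ensemble$sign[accept] <- eY$sign[accept]
  }
  if (any(bad)) ensemble$X[!accept & bad, ] <- X[!accept & bad, , drop = FALSE]
  if (any(bad)) {
    # refreshed caches for reinitialized-but-rejected walkers
    keep <- !accept & bad
    if (any(keep)) {
      ek <- psi_eval(wf, ensemble$X[keep, , drop = FALSE])
      ensemble$logabs[keep] <- ek$logabs
      ensemble$sign[keep] <- ek$sign
    }
  }
  ensemble$n_moves <- ensemble$n_moves + B
  ensemble$n_accept <- ensemble$n_accept + sum(accept)
  ensemble$acc_rate <- ensemble$n_accept / ensemble$n_moves
  ensemble
}

#' Adapt the Langevin step size toward the target acceptance
#'
#' Multiplicative adaptation toward acceptance 0.57 (the standard Langevin
#' optimal-scaling target): `delta <- delta * clip(acc, 0.3, 0.9) / 0.57`.
#' Requires at least 50 accumulated moves; a frozen ensemble (during
#' estimator evaluation windows) is returned unchanged so chains are
#' time-homogeneous while statistics are collected.
#'
#' @param ensemble a `walker_ensemble`.
#' @param target target acceptance rate.
#' @return ensemble with updated step size and reset counters.
#' @export
tune_step_size <- function(ensemble, target = 0.57) {
  if (ensemble$tuning_frozen) return(ensemble)
  if (ensemble$n_moves < 50L) return(ensemble)
  acc <- ensemble$n_accept / ensemble$n_moves
  ensemble$step <- ensemble$step * min(max(acc, 0.3), 0.9) / target
  ensemble$n_moves <- 0L
  ensemble$n_accept <- 0L
  # refresh the (frozen-during-evaluation) scale of the auxiliary global move
  ensemble$global_scale <- 2 * pmax(apply(ensemble$X, 2, stats::sd), 1e-3)
  ensemble
}

#' Auxiliary global move (symmetric random-walk Metropolis)
#'
#' A full-configuration Gaussian random-walk proposal at a scale comparable
#' to the walker cloud, accepted with the plain Metropolis ratio. Leaves
#' `|psi|^2` exactly invariant and restores ergodicity across nodal pockets
#' that the drifted Langevin kernel crosses only rarely. The proposal scale
#' is adapted together with the step size and frozen during evaluation
#' windows.
#'
#' @inheritParams langevin_step
#' @export
global_move <- function(ensemble, wf, system) {
  X <- ensemble$X
  B <- nrow(X); nd <- ncol(X)
  r <- with_rng_state(ensemble$rng, matrix(stats::rnorm(B * nd), B, nd))
  ensemble$rng <- r$state
  Y <- X + sweep(r$value, 2, ensemble$global_scale, `*`)
  eY <- psi_eval(wf, Y)
  log_alpha <- 2 * (eY$logabs - ensemble$logabs)
  log_alpha[eY$sign == 0 | !is.finite(eY$logabs)] <- -Inf
  r <- with_rng_state(ensemble$rng, stats::runif(B))
  ensemble$rng <- r$state
  accept <- log(r$value) < log_alpha
  if (any(accept)) {
    ensemble$X[accept, ] <- Y[accept, , drop = FALSE]
    ensemble$logabs[accept] <- eY$logabs[accept]
    ensemble$sign[accept] <- eY$sign[accept]
  }
  ensemble
}

#' Run several Langevin steps (with optional tuning)
#'
#' Convenience wrapper: `steps` moves, tuning every `tune_every` moves
#' unless the ensemble is frozen.
#'
#' @inheritParams langevin_step
#' @param steps number of moves.
#' @param tune_every tuning cadence in moves (0 = never).
#' @param global_every cadence of the auxiliary [global_move()] (0 = never).
#' @export
run_chain <- function(ensemble, wf, system, steps, tune_every = 0L,
                      global_every = 5L) {
  for (s in seq_len(steps)) {
    ensemble <- langevin_step(ensemble, wf, system)
    if (global_every > 0L && s %% global_every == 0L) {
      ensemble <- global_move(ensemble, wf, system)
    }
    if (tune_every > 0L && s %% tune_every == 0L) {
      ensemble <- tune_step_size(ensemble)
    }
  }
  ensemble
}

#' Freeze / unfreeze step-size adaptation
#' @param ensemble a `walker_ensemble`.
#' @param frozen logical.
#' @export
freeze_tuning <- function(ensemble, frozen = TRUE) {
  ensemble$tuning_frozen <- isTRUE(frozen)
  ensemble
}

#' Resynchronize cached wavefunction values after a parameter update
#' @param ensemble a `walker_ensemble`.
#' @param wf the updated wavefunction.
#' @export
resync_walkers <- function(ensemble, wf) {
  e <- psi_eval(wf, ensemble$X)
  ensemble$logabs <- e$logabs
  ensemble$sign <- e$sign
  ensemble
}
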