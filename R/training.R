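# Joint excited-state optimization: summed energy loss plus pairwise
# overlap penalties, per-state SGD with detached lower states, exponential
# smoothing of energy statistics, checkpointing, and variance matching.

#' Overlap penalty
#'
#' `penalty(S) = 1/(1 - min(|S|, s_max)) - 1`: exactly 0 at `S = 0`, linear
#' to first order near orthogonality (`|S| + |S|^2 + ...`), bounded below by
#' `S^2`, strictly increasing in `|S|`, and divergence-like as states
#' collapse (the clamp `s_max` keeps it finite exactly at collapse).
#'
#' @param S overlap value(s) in `[-1, 1]`.
#' @param s_max overlap clamp in (0.9, 1).
#' @export
overlap_penalty <- function(S, s_max = 0.999) {
  stopifnot(s_max > 0.9, s_max < 1)
  1 / (1 - pmin(abs(S), s_max)) - 1
}

#' @rdname overlap_penalty
#' @details `overlap_penalty_deriv` is the exact derivative with respect to
#'   `|S|`; zero in the clamped region.
#' @export
overlap_penalty_deriv <- function(S, s_max = 0.999) {
  ifelse(abs(S) < s_max, 1 / (1 - abs(S))^2, 0)
}

#' Joint penalized loss over n states
#'
#' `sum_i E_i[E_loc] + alpha * sum_{i > j} penalty(S_ij)` with the pairwise
#' terms enumerated over the strict lower triangle.
#'
#' @param wfs list of wavefunctions (state 0 first).
#' @param system a `vmc_system`.
#' @param batches list of `config_batch`es, one per state.
#' @param alpha penalty weight (Ha).
#' @param s_max overlap clamp.
#' @param cap_quantile ratio capping for the overlap estimates.
#' @return list with `total`, `energy_terms`, `penalty_terms` (named
#'   `"i>j"`, 0-based), `overlaps`.
#' @export
joint_loss <- function(wfs, system, batches, alpha = 1, s_max = 0.999,
                       cap_quantile = 0.999) {
  n <- length(wfs)
  e <- vapply(seq_len(n), function(i) {
    energy_estimate(wfs[[i]], system, batches[[i]])$value
  }, numeric(1))
  pterms <- numeric(0); overlaps <- numeric(0)
  if (n > 1) {
    for (i in 2:n) for (j in 1:(i - 1)) {
      S <- overlap_estimate(wfs[[i]], wfs[[j]], batches[[i]], batches[[j]],
                            cap_quantile = cap_quantile)$value
      nm <- sprintf("%d>%d", i - 1, j - 1)
      overlaps[nm] <- S
      pterms[nm] <- overlap_penalty(S, s_max)
    }
  }
  list(total = sum(e) + alpha * sum(pterms), energy_terms = e,
       penalty_terms = pterms, overlaps = overlaps)
}

#' Per-state gradients of the joint loss
#'
#' State 0 gets the plain energy gradient (unconstrained minimization);
#' state `i` gets the energy gradient plus `alpha * penalty'(S_ij) * dS_ij`
#' for every lower-lying `j < i`, with the lower state detached (treated as
#' constant). The penalty derivative is the exact derivative of the clamped
#' penalty; overlap gradients are norm-clipped.
#'
#' The penalty prefactor `penalty'(|S|) * sign(S)` and the overlap gradient
#' `dS` are estimated on independent half-batches: near orthogonality the
#' sign of the overlap estimate is symmetric noise, and decorrelating it
#' from the gradient factor removes the systematic drift that a correlated
#' product acquires at finite batch size (the small-batch bias regime).
#'
#' @inheritParams joint_loss
#' @param winsor_k local-energy winsorization (gradient path).
#' @param clip_at gradient-norm clip for penalty gradients.
#' @return list with `grads` (per-state vectors) and `overlaps`.
#' @export
gradient_assembly <- function(wfs, system, batches, alpha = 1, s_max = 0.999,
                              cap_quantile = 0.999, winsor_k = Inf,
                              clip_at = 10) {
  n <- length(wfs)
  grads <- vector("list", n)
  overlaps <- numeric(0)
  halves <- lapply(batches, function(b) {
    if (inherits(b, "walker_ensemble")) b <- batch_from_ensemble(b)
    B <- nrow(b$X)
    ia <- seq_len(B %/% 2L)
    list(a = config_batch(b$X[ia, , drop = FALSE], b$log_base[ia]),
         b = config_batch(b$X[-ia, , drop = FALSE], b$log_base[-ia]))
  })
  for (i in seq_len(n)) {
    g <- grad_energy(wfs[[i]], system, batches[[i]], winsor_k = winsor_k)
    if (i > 1 && alpha > 0) {
      for (j in 1:(i - 1)) {
        S_full <- overlap_estimate(wfs[[i]], wfs[[j]], batches[[i]],
                                   batches[[j]], cap_quantile = cap_quantile)
        overlaps[sprintf("%d>%d", i - 1, j - 1)] <- S_full$value
        S_a <- overlap_estimate(wfs[[i]], wfs[[j]], halves[[i]]$a,
                                halves[[j]]$a, cap_quantile = cap_quantile)
        go <- grad_overlap(wfs[[i]], wfs[[j]], halves[[i]]$b, halves[[j]]$b,
                           detach_lower = TRUE, cap_quantile = cap_quantile,
                           clip_at = clip_at)
        if (!go$zeroed && S_a$value != 0) {
          g <- g + alpha * overlap_penalty_deriv(S_a$value, s_max) *
            sign(S_a$value) * go$grad_i
        }
      }
    } else if (i > 1) {
      for (j in 1:(i - 1)) {
        S <- overlap_estimate(wfs[[i]], wfs[[j]], batches[[i]], batches[[j]],
                              cap_quantile = cap_quantile)$value
        overlaps[sprintf("%d>%d", i - 1, j - 1)] <- S
      }
    }
    grads[[i]] <- clip_norm(g, clip_at)   # total per-state stabilization
  }
  list(grads = grads, overlaps = overlaps)
}

#' Bias-corrected exponential moving average of a series
#'
#' `m_t = decay * m_{t-1} + (1 - decay) * x_t`, divided by `1 - decay^t` so
#' the smoothed series is defined (and unbiased for constants) from the
#' first iteration.
#'
#' @param x numeric series.
#' @param decay decay in (0, 1).
#' @export
ema_smooth <- function(x, decay = 0.99) {
  stopifnot(decay > 0, decay < 1)
  m <- numeric(length(x))
  acc <- 0
  for (t in seq_along(x)) {
    acc <- decay * acc + (1 - decay) * x[t]
    m[t] <- acc / (1 - decay^t)
  }
  m
}

#' Recompute the smoothed statistics of a training trace
#'
#' @param trace a `training_trace`.
#' @param decay EMA decay.
#' @return the trace with `energy_smooth` and `variance_smooth` rebuilt.
#' @export
smooth_statistics <- function(trace, decay = 0.99) {
  trace$energy_smooth <- apply(trace$energy, 2, ema_smooth, decay = decay)
  trace$variance_smooth <- apply(trace$variance, 2, ema_smooth, decay = decay)
  trace$decay <- decay
  trace
}

#' Variance matching of two states' checkpoints
#'
#' Identifies the state with the higher final smoothed energy variance; the
#' other state is rewound to the checkpointed iteration whose smoothed
#' variance is closest to that target (ties resolved to the latest such
#' iteration). If the target lies below the other state's entire series the
#' final checkpoints are kept and the pair is flagged unmatched.
#'
#' @param trace a `training_trace` (with smoothed statistics).
#' @param state_lo,state_hi 1-based state indices of the pair.
#' @return list with the matched checkpoint iterations `iter` (named by
#'   state), `rewound` (which state was rewound, or `NA`), and `matched`.
#' @export
variance_match <- function(trace, state_lo, state_hi) {
  cks <- trace$checkpoint_iters
  vs <- trace$variance_smooth
  final_iter <- nrow(vs)
  v_lo <- vs[final_iter, state_lo]
  v_hi <- vs[final_iter, state_hi]
  iters <- stats::setNames(c(final_iter, final_iter), c(state_lo, state_hi))
  if (v_lo == v_hi) {
    return(list(iter = iters, rewound = NA_integer_, matched = TRUE))
  }
  target <- max(v_lo, v_hi)
  rewind <- if (v_lo < v_hi) state_lo else state_hi
  series <- vs[cks, rewind]
  if (all(series < target)) {
    return(list(iter = iters, rewound = NA_integer_, matched = FALSE))
  }
  dist <- abs(series - target)
  best <- max(which(dist == min(dist)))   # ties -> latest checkpoint
  iters[as.character(rewind)] <- cks[best]
  list(iter = iters, rewound = rewind, matched = TRUE)
}

#' Restore a checkpointed wavefunction
#'
#' @param fit a result of [train_states()].
#' @param state 1-based state index.
#' @param iter checkpointed iteration.
#' @export
restore_checkpoint <- function(fit, state, iter) {
  key <- as.character(iter)
  cp <- fit$trace$checkpoints[[key]]
  if (is.null(cp)) stop(sprintf("no checkpoint at iteration %s", key))
  wf_set_params(fit$states[[state]], cp[[state]])
}

#' Jointly train n states with the overlap penalty
#'
#' The sample/estimate/step loop: each iteration advances every state's
#' Langevin chain by `decorr` decorrelation moves, estimates the batch
#' energy and the pairwise overlaps, assembles the penalized gradients
#' (lower states detached) and takes an SGD step per state. Energy mean and
#' variance are smoothed with a bias-corrected EMA; parameters are
#' checkpointed at a fixed cadence. Training aborts if any state's smoothed
#' energy rises by more than 1 Ha over 100 iterations (divergence guard).
#' Fully reproducible given `seed` (single-threaded).
#'
#' After the loop an exhaustive fixed-parameter evaluation pass produces the
#' final spectrum: energies with block-jackknife errors, pairwise overlaps,
#' transition dipole moments and oscillator strengths, and excitation
#' energies with and without variance matching.
#'
#' @param system a `vmc_system`.
#' @param wfs list of initial wavefunctions, ground state first.
#' @param n_iter number of training iterations.
#' @param batch_size walkers per state (the paper-scale default is 2000).
#' @param lr SGD learning rate (scalar or per-parameter named vector).
#' @param lr_decay if finite, the rate decays as `lr / (1 + t / lr_decay)`.
#' @param alpha penalty weight, or a linear ramp `list(start=, end=,
#'   iters=)`.
#' @param seed master seed; per-state chains derive independent streams.
#' @param burn burn-in steps at initialization.
#' @param decorr decorrelation moves between parameter updates.
#' @param checkpoint_every checkpoint cadence (iterations).
#' @param ema_decay EMA decay for the smoothed statistics.
#' @param s_max overlap clamp of the penalty.
#' @param cap_quantile ratio-capping quantile of the overlap estimators.
#' @param winsor_k local-energy winsorization width (gradient path).
#' @param clip_at penalty gradient-norm clip.
#' @param optimizer `"sgd"` (plain stochastic gradient descent) or `"sr"`
#'   (stochastic reconfiguration / natural gradient: the update solves
#'   `(S + sr_eps I) d = g` with `S` the batch covariance of the
#'   per-sample parameter gradients of `ln|psi|`, removing the
#'   parametrization ill-conditioning that plain SGD inherits).
#' @param sr_eps diagonal regularization of the reconfiguration matrix.
#' @param eval_samples total decorrelated samples per state for the final
#'   evaluation pass.
#' @param eval_decorr decorrelation moves between evaluation draws.
#' @param verbose print progress every 100 iterations?
#' @return object of class `vmc_fit`: `trace` (`training_trace`), `result`
#'   (`spectrum_result`), `states` (final wavefunctions), `ensembles`.
#' @export
train_states <- function(system, wfs, n_iter, batch_size = 2000L, lr = 0.05,
                         lr_decay = Inf,
                         alpha = 1, seed = 1L, burn = 200L, decorr = 10L,
                         checkpoint_every = 100L, ema_decay = 0.99,
                         s_max = 0.999, cap_quantile = 0.999, winsor_k = Inf,
                         clip_at = 10, optimizer = c("sr", "sgd"),
                         sr_eps = 0.01, eval_samples = 1e5,
                         eval_decorr = 10L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  n <- length(wfs)
  stopifnot(n >= 1, n_iter >= 1)
  alpha_at <- function(t) {
    if (is.list(alpha)) {
      frac <- min(1, t / alpha$iters)
      alpha$start + frac * (alpha$end - alpha$start)
    } else alpha
  }
  ensembles <- lapply(seq_len(n), function(i) {
    init_walkers(wfs[[i]], system, batch_size, seed = derive_seed(seed, i),
                 burn = burn)
  })
  energy <- variance <- matrix(NA_real_, n_iter, n)
  overlaps <- list()
  alphas <- numeric(n_iter)
  checkpoints <- list()
  checkpoint_iters <- integer(0)
  ema_e <- ema_v <- rep(0, n)
  energy_smooth <- variance_smooth <- matrix(NA_real_, n_iter, n)
  for (t in seq_len(n_iter)) {
    a_t <- alpha_at(t)
    alphas[t] <- a_t
    for (i in seq_len(n)) {
      ensembles[[i]] <- resync_walkers(ensembles[[i]], wfs[[i]])
      ensembles[[i]] <- run_chain(ensembles[[i]], wfs[[i]], system,
                                  steps = decorr, tune_every = 50L)
    }
    batches <- lapply(ensembles, batch_from_ensemble)
    for (i in seq_len(n)) {
      est <- energy_estimate(wfs[[i]], system, batches[[i]])
      energy[t, i] <- est$value
      variance[t, i] <- est$variance
    }
    ga <- gradient_assembly(wfs, system, batches, alpha = a_t, s_max = s_max,
                            cap_quantile = cap_quantile, winsor_k = winsor_k,
                            clip_at = clip_at)
    for (nm in names(ga$overlaps)) {
      if (is.null(overlaps[[nm]])) overlaps[[nm]] <- rep(NA_real_, n_iter)
      overlaps[[nm]][t] <- ga$overlaps[[nm]]
    }
    for (i in seq_len(n)) {
      free <- wf_free_mask(wfs[[i]])
      if (!any(free)) next
      theta <- wf_params(wfs[[i]])
      step_lr <- if (length(lr) > 1) lr[names(theta)] else lr
      if (is.finite(lr_decay)) step_lr <- step_lr / (1 + t / lr_decay)
      g <- ga$grads[[i]]
      if (optimizer == "sr") {
        Gp <- psi_pgrad(wfs[[i]], batches[[i]]$X)[, free, drop = FALSE]
        ok <- rowSums(!is.finite(Gp)) == 0
        Gp <- Gp[ok, , drop = FALSE]
        Gp <- .cap_pgrad_rows(Gp, 0.999)
        Gc <- sweep(Gp, 2, colMeans(Gp))
        Smat <- crossprod(Gc) / nrow(Gc)
        delta <- solve(Smat + sr_eps * diag(ncol(Smat)), g[free])
        delta <- clip_norm(delta, clip_at)
        theta[free] <- theta[free] - step_lr * delta
      } else {
        theta[free] <- theta[free] - (step_lr * g)[free]
      }
      wfs[[i]] <- wf_set_params(wfs[[i]], theta)
    }
    ema_e <- ema_decay * ema_e + (1 - ema_decay) * energy[t, ]
    ema_v <- ema_decay * ema_v + (1 - ema_decay) * variance[t, ]
    corr <- 1 - ema_decay^t
    energy_smooth[t, ] <- ema_e / corr
    variance_smooth[t, ] <- ema_v / corr
    if (t %% checkpoint_every == 0L || t == n_iter) {
      checkpoints[[as.character(t)]] <- lapply(wfs, wf_params)
      checkpoint_iters <- c(checkpoint_iters, t)
    }
    if (t > 100L) {
      rise <- energy_smooth[t, ] - energy_smooth[t - 100L, ]
      if (any(rise > 1)) {
        stop(structure(
          class = c("vmc_divergence", "error", "condition"),
          list(message = sprintf(
            "divergence guard: smoothed energy of state %d rose by %.2f Ha over 100 iterations",
            which.max(rise) - 1, max(rise)),
            call = sys.call(-1),
            trace = list(energy = energy[seq_len(t), , drop = FALSE],
                         variance = variance[seq_len(t), , drop = FALSE]))
        ))
      }
    }
    if (verbose && t %% 100L == 0L) {
      message(sprintf("iter %d: E = %s | max |S| = %.3f", t,
                      paste(sprintf("%.4f", energy[t, ]), collapse = " "),
                      if (length(ga$overlaps)) max(abs(ga$overlaps)) else 0))
    }
  }
  trace <- structure(
    list(energy = energy, variance = variance,
         energy_smooth = energy_smooth, variance_smooth = variance_smooth,
         overlaps = overlaps, alpha = alphas,
         checkpoints = checkpoints, checkpoint_iters = checkpoint_iters,
         decay = ema_decay),
    class = "training_trace"
  )
  fit <- structure(
    list(trace = trace, states = wfs, ensembles = ensembles,
         system = system, seed = seed),
    class = "vmc_fit"
  )
  fit$result <- evaluate_spectrum(fit, eval_samples = eval_samples,
                                  eval_decorr = eval_decorr,
                                  cap_quantile = cap_quantile)
  fit
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf("<training_trace: %d iterations, %d state(s), %d checkpoint(s)>\n",
              nrow(x$energy), ncol(x$energy), length(x$checkpoint_iters)))
  invisible(x)
}

#' @export
print.vmc_fit <- function(x, ...) {
  cat("<vmc_fit>\n")
  print(x$trace)
  if (!is.null(x$result)) print(x$result)
  invisible(x)
}

# draw `total` decorrelated samples from a state by advancing its (frozen)
# chain in blocks of the ensemble size
.exhaustive_sample <- function(wf, system, ensemble, total, decorr) {
  ensemble <- freeze_tuning(resync_walkers(ensemble, wf))
  B <- nrow(ensemble$X)
  blocks <- max(1L, ceiling(total / B))
  out <- vector("list", blocks)
  for (b in seq_len(blocks)) {
    ensemble <- run_chain(ensemble, wf, system, steps = decorr)
    out[[b]] <- ensemble$X
  }
  config_batch(do.call(rbind, out))
}

#' Exhaustive fixed-parameter evaluation of a trained fit
#'
#' Long fixed-parameter sampling of every state: energies with
#' block-jackknife errors, pairwise overlaps, transition dipole moments,
#' oscillator strengths, and excitation energies with and without variance
#' matching (matched checkpoints re-evaluated by fresh sampling).
#'
#' @param fit a `vmc_fit`.
#' @param eval_samples samples per state.
#' @param eval_decorr decorrelation moves between draws.
#' @param cap_quantile ratio-capping quantile.
#' @return object of class `spectrum_result`.
#' @export
evaluate_spectrum <- function(fit, eval_samples = 1e5, eval_decorr = 10L,
                              cap_quantile = 0.999) {
  system <- fit$system
  wfs <- fit$states
  n <- length(wfs)
  batches <- lapply(seq_len(n), function(i) {
    .exhaustive_sample(wfs[[i]], system, fit$ensembles[[i]],
                       eval_samples, eval_decorr)
  })
  energies <- lapply(seq_len(n), function(i) {
    est <- energy_estimate(wfs[[i]], system, batches[[i]])
    el <- local_energy(wfs[[i]], system, batches[[i]]$X, check = FALSE)
    el <- el[is.finite(el)]
    est$se <- jackknife_se(mean, el, blocks = 50L)
    est
  })
  pairs <- list()
  if (n > 1) {
    for (j in 1:(n - 1)) for (i in (j + 1):n) {
      S <- overlap_estimate(wfs[[i]], wfs[[j]], batches[[i]], batches[[j]],
                            cap_quantile = cap_quantile, se_blocks = 50L)
      de_raw <- energies[[i]]$value - energies[[j]]$value
      vm <- variance_match(fit$trace, j, i)
      de_matched <- de_raw
      matched_iters <- vm$iter
      if (!is.na(vm$rewound) && any(vm$iter < nrow(fit$trace$energy))) {
        ew <- numeric(2)
        for (k in 1:2) {
          st <- c(j, i)[k]
          it <- vm$iter[as.character(st)]
          if (it < nrow(fit$trace$energy)) {
            wf_k <- restore_checkpoint(fit, st, it)
            b_k <- .exhaustive_sample(wf_k, system, fit$ensembles[[st]],
                                      eval_samples, eval_decorr)
            ew[k] <- energy_estimate(wf_k, system, b_k)$value
          } else {
            ew[k] <- energies[[st]]$value
          }
        }
        de_matched <- ew[2] - ew[1]
      }
      tdm <- transition_dipole(wfs[[i]], wfs[[j]], batches[[i]], batches[[j]],
                               system, delta_e = de_matched,
                               cap_quantile = cap_quantile, se_blocks = 50L)
      pairs[[sprintf("%d-%d", j - 1, i - 1)]] <- list(
        lower = j - 1L, upper = i - 1L,
        overlap = S$value, overlap_se = S$se,
        excitation_raw = de_raw, excitation_matched = de_matched,
        variance_matched = vm$matched, matched_iters = matched_iters,
        tdm = tdm$d, d2 = tdm$d2,
        oscillator_strength = tdm$f
      )
    }
  }
  structure(
    list(energies = energies, pairs = pairs, n_states = n,
         eval_samples = eval_samples, seed = fit$seed),
    class = "spectrum_result"
  )
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result: %d state(s)>\n", x$n_states))
  for (i in seq_len(x$n_states)) {
    cat(sprintf("  state %d: E = %.6f +/- %.2g Ha (var %.3g)\n", i - 1,
                x$energies[[i]]$value, x$energies[[i]]$se,
                x$energies[[i]]$variance))
  }
  for (p in x$pairs) {
    cat(sprintf("  %d->%d: dE = %.6f Ha (matched %.6f), |S| = %.4f, f = %.4f\n",
                p$lower, p$upper, p$excitation_raw, p$excitation_matched,
                abs(p$overlap), p$oscillator_strength))
  }
  invisible(x)
}
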