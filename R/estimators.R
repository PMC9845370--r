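# Monte Carlo estimators over weighted configuration sets.
#
# A batch is a set of points plus an optional log base density. Points drawn
# from |psi|^2 of the owning state have no base density and get uniform
# weights; a frozen common point cloud (or a quadrature grid) carries its
# base density, and expectations are self-normalized importance-weighted:
# w_b ~ |psi(x_b)|^2 / base(x_b). On one shared cloud the covariance-form
# gradient below is the exact derivative of the overlap estimator, which is
# what the finite-difference validations exploit.

#' Weighted configuration batch
#'
#' @param X configuration matrix (points x N*d).
#' @param log_base optional log base density of the points (per row). `NULL`
#'   means the points are already distributed as `|psi|^2` of the state the
#'   batch belongs to. For a quadrature grid with node weights `w`, pass
#'   `-log(w)`.
#' @return an object of class `config_batch`.
#' @export
config_batch <- function(X, log_base = NULL) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (!is.null(log_base)) stopifnot(length(log_base) == nrow(X))
  structure(list(X = X, log_base = log_base), class = "config_batch")
}

#' Extract the current batch of a walker ensemble
#' @param ensemble a `walker_ensemble`.
#' @export
batch_from_ensemble <- function(ensemble) config_batch(ensemble$X)

# normalized weights of a batch under a state
.batch_weights <- function(batch, wf) {
  B <- nrow(batch$X)
  if (is.null(batch$log_base)) {
    rep(1 / B, B)
  } else {
    lw <- 2 * psi_eval(wf, batch$X)$logabs - batch$log_base
    lw <- lw - max(lw[is.finite(lw)])
    w <- exp(lw)
    w[!is.finite(w)] <- 0
    w / sum(w)
  }
}

.wmean <- function(x, w) sum(w * x)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2)
}

# ---- local operators -------------------------------------------------------

#' Local operators for mixed observables
#'
#' A local operator supplies the pointwise action `(O psi)(r) / psi(r)`.
#' `op_identity()` gives 1 (overlaps); `op_multiply(g)` a multiplicative
#' operator `g(r)`; `op_dipole(system, alpha, q)` the `alpha`-th Cartesian
#' component of the charge-weighted position operator `sum_k q r_k`;
#' `op_hamiltonian(system)` the Hamiltonian (action = local energy).
#'
#' @param g vectorized function of the configuration matrix.
#' @return an object of class `local_operator`.
#' @export
op_multiply <- function(g, name = "multiplicative") {
  structure(
    list(apply = function(wf, X) g(X), name = name),
    class = "local_operator"
  )
}

#' @rdname op_multiply
#' @export
op_identity <- function() {
  structure(
    list(apply = function(wf, X) rep(1, nrow(X)), name = "identity"),
    class = "local_operator"
  )
}

#' @rdname op_multiply
#' @param system a `vmc_system` (for particle count / Hamiltonian).
#' @param alpha Cartesian component index (1-based).
#' @param q charge per particle (`-1` for electrons).
#' @export
op_dipole <- function(system, alpha, q = -1) {
  N <- n_particles(system); d <- system_dim(system)
  stopifnot(alpha >= 1, alpha <= d)
  cols <- (seq_len(N) - 1L) * d + alpha
  structure(
    list(apply = function(wf, X) q * rowSums(X[, cols, drop = FALSE]),
         name = sprintf("dipole[%d]", alpha)),
    class = "local_operator"
  )
}

#' @rdname op_multiply
#' @export
op_hamiltonian <- function(system) {
  structure(
    list(apply = function(wf, X) local_energy(wf, system, X, check = FALSE),
         name = "hamiltonian"),
    class = "local_operator",
    system = system
  )
}

# cap a vector at the q-th percentile of its absolute value (NA/Inf kept
# out of the threshold; they are dropped downstream)
.cap_ratio <- function(t, q) {
  if (q >= 1) return(list(t = t, rate = 0))
  fin <- is.finite(t)
  if (!any(fin)) return(list(t = t, rate = 0))
  thr <- stats::quantile(abs(t[fin]), q, names = FALSE, type = 7)
  capped <- fin & abs(t) > thr
  t[capped] <- sign(t[capped]) * thr
  t[!fin & !is.na(t)] <- sign(t[!fin & !is.na(t)]) * thr  # +/- Inf -> cap
  list(t = t, rate = mean(capped))
}

# ---- energy ----------------------------------------------------------------

#' Monte Carlo energy estimate
#'
#' Mean and standard error of the local energy over a batch, plus the batch
#' variance (used by variance matching). Non-finite local energies are
#' excluded and counted; more than 1% exclusions raises a warning. The
#' reported estimate is the plain (weighted) mean — winsorization is applied
#' on the gradient path only.
#'
#' @param wf wavefunction.
#' @param system a `vmc_system`.
#' @param batch a `config_batch` drawn from `|psi|^2` (or weighted).
#' @return object of class `scalar_estimate` with `value`, `se`,
#'   `variance`, `n_eff`, `n_excluded`.
#' @export
energy_estimate <- function(wf, system, batch) {
  if (inherits(batch, "walker_ensemble")) batch <- batch_from_ensemble(batch)
  w <- .batch_weights(batch, wf)
  el <- local_energy(wf, system, batch$X, check = FALSE)
  ok <- is.finite(el)
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    w <- w[ok] / sum(w[ok])
    el <- el[ok]
    if (n_excl > 0.01 * length(ok)) {
      warning(sprintf("energy_estimate: %d/%d local energies non-finite",
                      n_excl, length(ok)))
    }
  }
  v <- .wvar(el, w)
  n_eff <- 1 / sum(w^2)
  structure(
    list(value = .wmean(el, w), se = sqrt(v / n_eff), variance = v,
         n_eff = n_eff, n_excluded = n_excl),
    class = "scalar_estimate"
  )
}

#' @export
print.scalar_estimate <- function(x, ...) {
  cat(sprintf("<scalar_estimate: %.6f +/- %.2g (n_eff %.0f)>\n",
              x$value, x$se, x$n_eff))
  invisible(x)
}

# ---- mixed observables and overlaps ----------------------------------------

# signed ratio psi_num / psi_den at the rows of X
.psi_ratio <- function(wf_num, wf_den, X) {
  en <- psi_eval(wf_num, X)
  ed <- psi_eval(wf_den, X)
  r <- en$sign * ed$sign * exp(en$logabs - ed$logabs)
  r[ed$sign == 0] <- NA_real_
  r
}

# core of Eq.-15-style estimates; returns directional means and diagnostics
.mixed_core <- function(op, wf_i, wf_j, batch_i, batch_j, cap_quantile) {
  if (inherits(batch_i, "walker_ensemble")) batch_i <- batch_from_ensemble(batch_i)
  if (inherits(batch_j, "walker_ensemble")) batch_j <- batch_from_ensemble(batch_j)
  w_i <- .batch_weights(batch_i, wf_i)
  w_j <- .batch_weights(batch_j, wf_j)
  r_ji <- .psi_ratio(wf_j, wf_i, batch_i$X)   # psi_j / psi_i on batch i
  r_ij <- .psi_ratio(wf_i, wf_j, batch_j$X)
  ci <- .cap_ratio(r_ji, cap_quantile)
  cj <- .cap_ratio(r_ij, cap_quantile)
  a_j <- op$apply(wf_j, batch_i$X)            # (O psi_j)/psi_j on batch i
  a_i <- op$apply(wf_i, batch_j$X)
  t_i <- a_j * ci$t
  t_j <- a_i * cj$t
  # points carrying zero weight under the owning state (e.g. quadrature
  # nodes on its nodal set) cannot contribute and may hold Inf ratios
  ok_i <- is.finite(t_i) & w_i > 0
  ok_j <- is.finite(t_j) & w_j > 0
  list(
    t_i = t_i[ok_i], t_j = t_j[ok_j],
    w_i = w_i[ok_i] / sum(w_i[ok_i]), w_j = w_j[ok_j] / sum(w_j[ok_j]),
    m_i = .wmean(t_i[ok_i], w_i[ok_i] / sum(w_i[ok_i])),
    m_j = .wmean(t_j[ok_j], w_j[ok_j] / sum(w_j[ok_j])),
    cap_rate = c(i = ci$rate, j = cj$rate),
    ok_i = ok_i, ok_j = ok_j
  )
}

.geometric_mean_estimate <- function(core) {
  m_i <- core$m_i; m_j <- core$m_j
  sign_agree <- sign(m_i) == sign(m_j) && m_i != 0 && m_j != 0
  value <- if (sign_agree) sign(m_i) * sqrt(m_i * m_j) else 0
  list(value = value, sign_agree = sign_agree)
}

#' Norm-free Monte Carlo estimate of a mixed observable
#'
#' Estimates `O_ij = <psi_i|O|psi_j> / (N_i N_j)` for unnormalized states as
#' the signed geometric mean of the two directional ratio expectations,
#' `sgn(E_i[O psi_j / psi_i]) * sqrt(E_i[O psi_j/psi_i] E_j[O psi_i/psi_j])`.
#' With the identity operator this is exactly the pairwise overlap; the
#' wavefunction norms cancel, so the estimate is invariant under rescaling
#' either state. If the two directional estimates disagree in sign the
#' states are reported orthogonal (value 0, `sign_agree = FALSE`). Ratios
#' are capped at the `cap_quantile` percentile of their absolute value
#' (heavy tails near nodes); the capped fraction is reported.
#'
#' @param op a `local_operator`.
#' @param wf_i,wf_j the two states.
#' @param batch_i,batch_j batches from `|psi_i|^2` and `|psi_j|^2` (or
#'   weighted point sets).
#' @param cap_quantile ratio-capping quantile in (0, 1]; 1 disables capping.
#' @param se_blocks jackknife block count for the standard error.
#' @return object of class `mixed_estimate` with `value`, `se`, directional
#'   means `mean_i`/`mean_j`, `sign_agree`, `cap_rate`.
#' @export
mixed_observable <- function(op, wf_i, wf_j, batch_i, batch_j,
                             cap_quantile = 0.999, se_blocks = 20L) {
  core <- .mixed_core(op, wf_i, wf_j, batch_i, batch_j, cap_quantile)
  gm <- .geometric_mean_estimate(core)
  est_fun <- function(x, y) {
    mi <- mean(x); mj <- mean(y)
    if (sign(mi) != sign(mj) || mi == 0) return(0)
    sign(mi) * sqrt(mi * mj)
  }
  se <- jackknife_se(est_fun, core$t_i, core$t_j, blocks = se_blocks)
  # near orthogonality the jackknife collapses (sign-disagreeing blocks map
  # to zero); the geometric mean of the directional-mean standard errors is
  # the natural scale of the estimate there and serves as a floor
  se_dir <- sqrt(se_mean(core$t_i) * se_mean(core$t_j))
  se <- max(se, se_dir, na.rm = TRUE)
  structure(
    list(value = gm$value, se = se, mean_i = core$m_i, mean_j = core$m_j,
         sign_agree = gm$sign_agree, cap_rate = core$cap_rate,
         operator = op$name),
    class = "mixed_estimate"
  )
}

#' @export
print.mixed_estimate <- function(x, ...) {
  cat(sprintf("<mixed_estimate [%s]: %.6f +/- %.2g%s>\n",
              x$operator, x$value, x$se,
              if (!x$sign_agree) " (signs disagree -> 0)" else ""))
  invisible(x)
}

#' Pairwise overlap of two unnormalized states
#'
#' The Eq.-8-style estimator: [mixed_observable()] with the identity
#' operator. `S_ii = 1` exactly when both arguments are the same state on
#' the same batch.
#'
#' @inheritParams mixed_observable
#' @return object of class `overlap_estimate` (a `mixed_estimate`).
#' @export
overlap_estimate <- function(wf_i, wf_j, batch_i, batch_j,
                             cap_quantile = 0.999, se_blocks = 20L) {
  est <- mixed_observable(op_identity(), wf_i, wf_j, batch_i, batch_j,
                          cap_quantile = cap_quantile, se_blocks = se_blocks)
  class(est) <- c("overlap_estimate", class(est))
  est
}

#' Transition dipole moment between two states
#'
#' Component-wise norm-free mixed estimates of the charge-weighted position
#' operator (`q = -1` per electron). The global sign of the vector is not an
#' observable (phase freedom); only `|d|` and the dipole strength `d^2`
#' carry meaning.
#'
#' @inheritParams mixed_observable
#' @param system a `vmc_system`.
#' @param delta_e excitation energy `E_j - E_i` (Ha), used for the
#'   oscillator strength.
#' @param q charge per particle.
#' @return object of class `transition_moment`: components `d` (with SEs
#'   `d_se`), dipole strength `d2`, `delta_e`, oscillator strength `f`.
#' @export
transition_dipole <- function(wf_i, wf_j, batch_i, batch_j, system, delta_e,
                              q = -1, cap_quantile = 0.999, se_blocks = 20L) {
  d <- system_dim(system)
  comps <- lapply(seq_len(d), function(alpha) {
    mixed_observable(op_dipole(system, alpha, q), wf_i, wf_j,
                     batch_i, batch_j, cap_quantile, se_blocks)
  })
  dvec <- vapply(comps, `[[`, numeric(1), "value")
  dse <- vapply(comps, `[[`, numeric(1), "se")
  d2 <- sum(dvec^2)
  structure(
    list(d = dvec, d_se = dse, d2 = d2, delta_e = delta_e,
         f = oscillator_strength(delta_e = delta_e, d2 = d2),
         components = comps),
    class = "transition_moment"
  )
}

#' @export
print.transition_moment <- function(x, ...) {
  cat(sprintf("<transition_moment: |d| = %.4f e*bohr, d2 = %.4f, dE = %.4f Ha, f = %.4f>\n",
              sqrt(x$d2), x$d2, x$delta_e, x$f))
  invisible(x)
}

#' Oscillator strength
#'
#' `f_ij = (2/3) * dE * d_ij^2` in atomic units; pure arithmetic. A negative
#' `dE` flags an upstream state-ordering issue (attribute `"flagged"`).
#'
#' @param tm a `transition_moment`, or supply `delta_e` and `d2` directly.
#' @param delta_e excitation energy (Ha).
#' @param d2 dipole strength (e^2 bohr^2).
#' @export
oscillator_strength <- function(tm = NULL, delta_e = NULL, d2 = NULL) {
  if (!is.null(tm)) {
    delta_e <- tm$delta_e
    d2 <- tm$d2
  }
  f <- (2 / 3) * delta_e * d2
  if (is.finite(delta_e) && delta_e < 0) attr(f, "flagged") <- "negative excitation energy"
  f
}
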