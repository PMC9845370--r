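# Parameter-space gradients of the loss terms: the covariance-form energy
# gradient and the overlap (mixed-observable) gradient, both depending only
# on first parameter-derivatives of ln|psi|.

# column-wise E_w[(t - E_w[t]) * G]
.wcov_centered <- function(t, G, w) {
  mt <- .wmean(t, w)
  colSums(w * ((t - mt) * G))
}

# cap per-sample parameter-gradient rows at the q-th percentile of their
# norms; ln|psi| parameter-derivatives diverge at nodes for families that
# divide by the wavefunction, and the covariance estimator inherits the
# heavy tail unless the rows are bounded. The cap vanishes from the fixed
# point: at an eigenstate the centered local energy is zero everywhere.
.cap_pgrad_rows <- function(G, q = 0.99) {
  if (q >= 1 || nrow(G) < 10L) return(G)
  nrm <- sqrt(rowSums(G * G))
  thr <- stats::quantile(nrm[is.finite(nrm)], q, names = FALSE, type = 7)
  if (!is.finite(thr) || thr <= 0) return(G)
  over <- which(is.finite(nrm) & nrm > thr)
  if (length(over)) G[over, ] <- G[over, , drop = FALSE] * (thr / nrm[over])
  G
}

#' Energy gradient (covariance form)
#'
#' `grad E = 2 E[(E_loc - E[E_loc]) * d ln|psi| / d theta]` over a batch
#' from `|psi|^2`. Local energies are winsorized at median +/- `winsor_k` *
#' mean-absolute-deviation before entering the covariance (gradient path
#' only; `winsor_k = Inf` disables). Frozen parameter groups receive exact
#' zeros; non-finite per-sample terms are excluded and counted in the
#' `"n_excluded"` attribute.
#'
#' @param wf wavefunction.
#' @param system a `vmc_system`.
#' @param batch a `config_batch` or `walker_ensemble`.
#' @param winsor_k winsorization width in mean-absolute-deviations.
#' @param pgrad_cap quantile cap on per-sample parameter-gradient row norms
#'   (1 disables; gradient path only).
#' @return numeric gradient over the full parameter vector.
#' @export
grad_energy <- function(wf, system, batch, winsor_k = Inf, pgrad_cap = 0.99) {
  if (inherits(batch, "walker_ensemble")) batch <- batch_from_ensemble(batch)
  w <- .batch_weights(batch, wf)
  el <- local_energy(wf, system, batch$X, check = FALSE)
  G <- psi_pgrad(wf, batch$X)
  ok <- is.finite(el) & rowSums(!is.finite(G)) == 0
  n_excl <- sum(!ok)
  el <- el[ok]; G <- G[ok, , drop = FALSE]; w <- w[ok] / sum(w[ok])
  if (is.finite(winsor_k)) el <- winsorize_mad(el, winsor_k)
  G <- .cap_pgrad_rows(G, pgrad_cap)
  g <- 2 * .wcov_centered(el, G, w)
  names(g) <- names(wf_params(wf))
  attr(g, "n_excluded") <- n_excl
  g
}

#' Overlap / mixed-observable gradient (covariance form)
#'
#' The norm-free gradient of the geometric-mean estimator with respect to
#' the parameters of both states:
#' `d O_ij = (1/O_ij) { E_i[(O psi_j/psi_i - E_i[.]) d ln|psi_i|] E_j[O psi_i/psi_j] + (i <-> j) }`.
#' With `detach_lower = TRUE` the lower state `j` is treated as a constant
#' and only the state-`i` gradient is returned (the training loop detaches
#' overlaps against lower-lying states). When the two arguments are the same
#' state on the same batch and `op` is the Hamiltonian, the result reduces
#' bit-exactly to [grad_energy()] on that batch.
#'
#' A total gradient-norm clip (`clip_at`, default 10) stabilizes the penalty
#' path. If `|O_ij|` falls below `zero_tol` (or the directional signs
#' disagree), the gradient is defined as zero. In the same spirit — states
#' whose overlap is statistically indistinguishable from zero are treated
#' as orthogonal — the gradient is also zeroed when `|O_ij|` is below
#' `se_gate` block-jackknife standard errors: otherwise the penalty chases
#' the estimator's own sampling noise and biases nearly-converged excited
#' states (the small-batch regime).
#'
#' @inheritParams mixed_observable
#' @param detach_lower treat state `j` as constant?
#' @param winsor_k winsorization for Hamiltonian actions (as [grad_energy()]).
#' @param clip_at maximum gradient norm (`Inf` disables).
#' @param zero_tol overlap magnitude below which the gradient is zeroed.
#' @param se_gate noise-gate width in standard errors (0 disables).
#' @param op local operator (identity for the overlap penalty).
#' @return list with `grad_i`, `grad_j` (`NULL` if detached), `value` (the
#'   overlap estimate used), `sign_agree`, `zeroed`.
#' @export
grad_overlap <- function(wf_i, wf_j, batch_i, batch_j,
                         detach_lower = FALSE, op = op_identity(),
                         cap_quantile = 0.999, winsor_k = Inf,
                         clip_at = 10, zero_tol = 1e-8, pgrad_cap = 0.99,
                         se_gate = 2) {
  if (inherits(batch_i, "walker_ensemble")) batch_i <- batch_from_ensemble(batch_i)
  if (inherits(batch_j, "walker_ensemble")) batch_j <- batch_from_ensemble(batch_j)
  same_state <- identical(wf_i, wf_j) && identical(batch_i, batch_j)
  if (same_state && op$name == "hamiltonian") {
    # i = j with the Hamiltonian: Eq.-17 energy gradient, bit-exact
    g <- grad_energy(wf_i, attr(op, "system"), batch_i, winsor_k, pgrad_cap)
    return(list(grad_i = g, grad_j = if (detach_lower) NULL else g,
                value = NA_real_, sign_agree = TRUE, zeroed = FALSE))
  }
  core <- .mixed_core(op, wf_i, wf_j, batch_i, batch_j, cap_quantile)
  if (op$name == "hamiltonian" && is.finite(winsor_k)) {
    core$t_i <- winsorize_mad(core$t_i, winsor_k)
    core$t_j <- winsorize_mad(core$t_j, winsor_k)
    core$m_i <- .wmean(core$t_i, core$w_i)
    core$m_j <- .wmean(core$t_j, core$w_j)
  }
  gm <- .geometric_mean_estimate(core)
  O <- gm$value
  p_i <- length(wf_params(wf_i)); p_j <- length(wf_params(wf_j))
  gate <- zero_tol
  if (se_gate > 0) {
    se <- jackknife_se(function(x, y) {
      mi <- mean(x); mj <- mean(y)
      if (sign(mi) != sign(mj) || mi == 0) 0 else sign(mi) * sqrt(mi * mj)
    }, core$t_i, core$t_j, blocks = 20L)
    if (is.finite(se)) gate <- max(gate, se_gate * se)
  }
  if (!gm$sign_agree || abs(O) < gate) {
    return(list(grad_i = numeric(p_i),
                grad_j = if (detach_lower) NULL else numeric(p_j),
                value = O, sign_agree = gm$sign_agree, zeroed = TRUE))
  }
  G_i <- .cap_pgrad_rows(psi_pgrad(wf_i, batch_i$X)[core$ok_i, , drop = FALSE],
                         pgrad_cap)
  grad_i <- (1 / O) * .wcov_centered(core$t_i, G_i, core$w_i) * core$m_j
  grad_i <- clip_norm(grad_i, clip_at)
  names(grad_i) <- names(wf_params(wf_i))
  grad_j <- NULL
  if (!detach_lower) {
    G_j <- .cap_pgrad_rows(psi_pgrad(wf_j, batch_j$X)[core$ok_j, , drop = FALSE],
                           pgrad_cap)
    grad_j <- (1 / O) * .wcov_centered(core$t_j, G_j, core$w_j) * core$m_i
    grad_j <- clip_norm(grad_j, clip_at)
    names(grad_j) <- names(wf_params(wf_j))
  }
  list(grad_i = grad_i, grad_j = grad_j, value = O,
       sign_agree = gm$sign_agree, zeroed = FALSE)
}
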