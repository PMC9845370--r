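# The trial-wavefunction contract. A wavefunction object evaluates in
# sign/log form and carries exact analytic derivatives: coordinate gradient
# and Laplacian of ln|psi| (for local energies and Langevin drift) and the
# parameter gradient of ln|psi| (for stochastic optimization). Frozen
# parameter groups receive exactly zero gradient.

#' Evaluate a wavefunction in sign/log form
#'
#' @param wf a wavefunction object.
#' @param X configuration matrix, one walker per row.
#' @return list with `sign` (integer vector in -1/0/+1) and `logabs`
#'   (numeric vector; `-Inf` exactly on nodes).
#' @export
psi_eval <- function(wf, X) UseMethod("psi_eval")

#' Coordinate gradient of `ln|psi|`
#' @inheritParams psi_eval
#' @return matrix (walkers x N*d) of first derivatives.
#' @export
psi_grad <- function(wf, X) UseMethod("psi_grad")

#' Coordinate Laplacian of `ln|psi|`
#' @inheritParams psi_eval
#' @return numeric vector: `sum_k d^2 ln|psi| / dx_k^2` per walker.
#' @export
psi_lap <- function(wf, X) UseMethod("psi_lap")

#' Parameter gradient of `ln|psi|`
#' @inheritParams psi_eval
#' @return matrix (walkers x n_params); columns of frozen parameters are
#'   exactly zero.
#' @export
psi_pgrad <- function(wf, X) UseMethod("psi_pgrad")

#' Get / set the parameter vector of a wavefunction
#' @param wf a wavefunction object.
#' @export
wf_params <- function(wf) UseMethod("wf_params")

#' @export
wf_params.default <- function(wf) wf$theta

#' @rdname wf_params
#' @param theta replacement parameter vector (same length and order).
#' @export
wf_set_params <- function(wf, theta) UseMethod("wf_set_params")

#' @export
wf_set_params.default <- function(wf, theta) {
  stopifnot(length(theta) == length(wf$theta))
  wf$theta <- stats::setNames(as.numeric(theta), names(wf$theta))
  wf
}

#' Trainable-parameter mask of a wavefunction
#' @param wf a wavefunction object.
#' @return logical vector, `TRUE` for trainable entries.
#' @export
wf_free_mask <- function(wf) UseMethod("wf_free_mask")

#' @export
wf_free_mask.default <- function(wf) {
  if (is.null(wf$free)) rep(TRUE, length(wf$theta)) else wf$free
}

#' @export
print.wavefunction <- function(x, ...) {
  cat(sprintf("<%s: %d parameter(s), %d trainable>\n",
              class(x)[1], length(wf_params(x)), sum(wf_free_mask(x))))
  invisible(x)
}

# mask frozen columns to exact zeros
.mask_pgrad <- function(wf, G) {
  free <- wf_free_mask(wf)
  if (!all(free)) G[, !free] <- 0
  G
}

#' Linear combination of wavefunctions
#'
#' `psi = sum_k a_k psi_k`, evaluated stably in the log domain. The component
#' states are frozen; the combination itself carries no trainable
#' parameters. Used for exact mixtures of eigenstates.
#'
#' @param coefs numeric coefficients `a_k`.
#' @param wfs list of wavefunction objects on the same configuration space.
#' @return a wavefunction object.
#' @export
linear_combo_wavefunction <- function(coefs, wfs) {
  stopifnot(length(coefs) == length(wfs), length(wfs) >= 1)
  structure(
    list(coefs = as.numeric(coefs), wfs = wfs,
         theta = numeric(0), free = logical(0)),
    class = c("linear_combo_wavefunction", "wavefunction")
  )
}

# relative signed weights w_k = a_k psi_k / psi, one column per component
.combo_weights <- function(wf, X) {
  K <- length(wf$wfs)
  B <- nrow(X)
  sg <- matrix(0, B, K); la <- matrix(-Inf, B, K)
  for (k in seq_len(K)) {
    e <- psi_eval(wf$wfs[[k]], X)
    sg[, k] <- e$sign * sign(wf$coefs[k])
    la[, k] <- e$logabs + log(abs(wf$coefs[k]))
  }
  # row-wise signed log-sum-exp, vectorized over walkers
  M <- do.call(pmax, c(lapply(seq_len(K), function(k) la[, k]), list(-Inf)))
  M[!is.finite(M)] <- 0
  terms <- sg * exp(la - M)
  tot <- rowSums(terms)
  tot_sign <- sign(tot)
  tot_log <- ifelse(tot == 0, -Inf, M + log(abs(tot)))
  W <- terms / ifelse(tot == 0, 1, tot)
  W[tot == 0, ] <- 0
  list(sign = tot_sign, logabs = tot_log, W = W)
}

#' @export
psi_eval.linear_combo_wavefunction <- function(wf, X) {
  cw <- .combo_weights(wf, X)
  list(sign = cw$sign, logabs = cw$logabs)
}

#' @export
psi_grad.linear_combo_wavefunction <- function(wf, X) {
  cw <- .combo_weights(wf, X)
  G <- matrix(0, nrow(X), ncol(X))
  # derivatives are defined away from the nodes of the components: a point
  # exactly on a component's own node makes w_k * grad ln psi_k a genuine
  # 0 * Inf and the result is NaN there (a measure-zero set; samplers never
  # land on it). Components with a zero coefficient contribute exactly 0.
  for (k in seq_along(wf$wfs)) {
    if (wf$coefs[k] == 0) next
    G <- G + cw$W[, k] * psi_grad(wf$wfs[[k]], X)
  }
  G
}

#' @export
psi_lap.linear_combo_wavefunction <- function(wf, X) {
  cw <- .combo_weights(wf, X)
  # laplacian(psi)/psi = sum_k w_k (lap ln psi_k + |grad ln psi_k|^2)
  lap_over_psi <- numeric(nrow(X))
  for (k in seq_along(wf$wfs)) {
    if (wf$coefs[k] == 0) next
    gk <- psi_grad(wf$wfs[[k]], X)
    lk <- psi_lap(wf$wfs[[k]], X)
    lap_over_psi <- lap_over_psi + cw$W[, k] * (lk + rowSums(gk * gk))
  }
  G <- psi_grad(wf, X)
  lap_over_psi - rowSums(G * G)
}

#' @export
psi_pgrad.linear_combo_wavefunction <- function(wf, X) {
  matrix(0, nrow(X), 0)
}

#' Wavefunction rescaled by a positive constant
#'
#' Multiplies a state by `scale` (log-domain shift). Estimators must be
#' invariant under this operation; it exists to make that testable.
#'
#' @param wf a wavefunction object.
#' @param scale positive scale factor.
#' @export
scaled_wavefunction <- function(wf, scale) {
  stopifnot(scale > 0)
  structure(
    list(base = wf, logscale = log(scale),
         theta = wf_params(wf), free = wf_free_mask(wf)),
    class = c("scaled_wavefunction", "wavefunction")
  )
}

#' @export
psi_eval.scaled_wavefunction <- function(wf, X) {
  e <- psi_eval(wf$base, X)
  list(sign = e$sign, logabs = e$logabs + wf$logscale)
}

#' @export
psi_grad.scaled_wavefunction <- function(wf, X) psi_grad(wf$base, X)

#' @export
psi_lap.scaled_wavefunction <- function(wf, X) psi_lap(wf$base, X)

#' @export
psi_pgrad.scaled_wavefunction <- function(wf, X) psi_pgrad(wf$base, X)

#' @export
wf_set_params.scaled_wavefunction <- function(wf, theta) {
  wf$base <- wf_set_params(wf$base, theta)
  wf$theta <- wf_params(wf$base)
  wf
}
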