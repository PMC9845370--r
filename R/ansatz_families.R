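# Closed-form ansatz families with exact analytic derivatives. These are the
# workhorses of the desk-scale validations: a polynomial-times-Gaussian
# family in 1D (spans every harmonic-trap eigenstate), a radial
# polynomial-times-exponential family in 3D (spans the hydrogenic s states),
# exact eigenstate constructors, and a cubic-spline wrapper around grid
# eigenfunctions.

# ---- polynomial evaluation helpers -----------------------------------------

.polyval <- function(coef, x) {
  # coef[k+1] multiplies x^k
  coef <- unname(coef)
  y <- numeric(length(x))
  for (k in rev(seq_along(coef))) y <- y * x + coef[k]
  y
}

.polyderiv <- function(coef) {
  K <- length(coef) - 1L
  if (K < 1L) return(0)
  coef[-1] * seq_len(K)
}

# ---- 1D polynomial x Gaussian family ---------------------------------------

#' Polynomial-times-Gaussian trial wavefunction (1D)
#'
#' `psi(x) = P(x) * exp(-a x^2 / 2 + b x)` with `P(x) = sum_k c_k x^k` and
#' `a = exp(log_a) > 0`. The family contains every eigenstate of the 1D
#' harmonic trap (Hermite functions), so penalty training can reach the
#' exact spectrum; all derivatives (coordinates and parameters) are
#' closed-form.
#'
#' @param coef polynomial coefficients `c_0, ..., c_K`.
#' @param a Gaussian width parameter (> 0); stored internally as `log a`.
#' @param b linear tilt.
#' @param free logical mask over `(coef, log_a, b)`; default all trainable.
#' @return a wavefunction object.
#' @examples
#' wf <- poly_gauss_wavefunction(c(1, 0.2), a = 1)
#' @export
poly_gauss_wavefunction <- function(coef, a = 1, b = 0, free = NULL) {
  stopifnot(a > 0, length(coef) >= 1)
  theta <- c(coef, log(a), b)
  names(theta) <- c(paste0("c", seq_along(coef) - 1L), "log_a", "b")
  if (is.null(free)) free <- rep(TRUE, length(theta))
  stopifnot(length(free) == length(theta))
  structure(
    list(theta = theta, free = free, K = length(coef) - 1L),
    class = c("poly_gauss_wavefunction", "wavefunction")
  )
}

.pg_parts <- function(wf, X) {
  x <- X[, 1L]
  K <- wf$K
  coef <- wf$theta[seq_len(K + 1L)]
  a <- exp(wf$theta[["log_a"]])
  b <- wf$theta[["b"]]
  P <- .polyval(coef, x)
  d1 <- .polyderiv(coef)
  Pp <- .polyval(d1, x)
  Ppp <- .polyval(.polyderiv(d1), x)
  list(x = x, coef = coef, a = a, b = b, P = P, Pp = Pp, Ppp = Ppp)
}

#' @export
psi_eval.poly_gauss_wavefunction <- function(wf, X) {
  p <- .pg_parts(wf, X)
  list(sign = sign(p$P),
       logabs = ifelse(p$P == 0, -Inf,
                       log(abs(p$P)) - p$a * p$x^2 / 2 + p$b * p$x))
}

#' @export
psi_grad.poly_gauss_wavefunction <- function(wf, X) {
  p <- .pg_parts(wf, X)
  matrix(p$Pp / p$P - p$a * p$x + p$b, ncol = 1L)
}

#' @export
psi_lap.poly_gauss_wavefunction <- function(wf, X) {
  p <- .pg_parts(wf, X)
  p$Ppp / p$P - (p$Pp / p$P)^2 - p$a
}

#' @export
psi_pgrad.poly_gauss_wavefunction <- function(wf, X) {
  p <- .pg_parts(wf, X)
  G <- cbind(
    vapply(0:wf$K, function(k) p$x^k / p$P, numeric(length(p$x))),
    -p$a * p$x^2 / 2,   # d/d log_a
    p$x                 # d/d b
  )
  colnames(G) <- names(wf$theta)
  .mask_pgrad(wf, G)
}

#' Exact harmonic-trap eigenstate (1D)
#'
#' The normalized `n`-th Hermite function for frequency `omega`, returned as
#' a frozen [poly_gauss_wavefunction()]. Exact energy `(n + 1/2) * omega`.
#'
#' @param n quantum number (0-based).
#' @param omega trap frequency.
#' @export
harmonic_eigenstate <- function(n, omega = 1) {
  stopifnot(n >= 0, omega > 0)
  # physicists' Hermite coefficients by recurrence
  h <- list(c(1), c(0, 2))
  if (n >= 2) {
    for (m in 2:n) {
      prev <- h[[m]]; prev2 <- h[[m - 1]]
      hm <- c(0, 2 * prev)
      hm[seq_along(prev2)] <- hm[seq_along(prev2)] - 2 * (m - 1) * prev2
      h[[m + 1]] <- hm
    }
  }
  coef <- h[[n + 1]] * sqrt(omega)^(seq_len(n + 1) - 1)
  norm <- (omega / pi)^0.25 / sqrt(2^n * factorial(n))
  wf <- poly_gauss_wavefunction(coef * norm, a = omega, b = 0)
  wf$free[] <- FALSE
  wf
}

# ---- 3D radial polynomial x exponential family -----------------------------

#' Radial polynomial-times-exponential trial wavefunction (3D)
#'
#' `psi(r) = A(x, y, z) * P(r) * exp(-alpha r)` for a single electron in 3D,
#' with `A = 1` (s symmetry) or `A = z` (p_z symmetry) and `P(r) = sum_k
#' c_k r^k`. The family contains the exact hydrogenic 1s/2s/2p_z states, so
#' joint penalty training on the hydrogen atom can reach the exact
#' excitation energy. `alpha = exp(log_alpha)` is trainable.
#'
#' @param coef radial polynomial coefficients.
#' @param alpha exponential decay (> 0).
#' @param angular `"s"` or `"pz"`.
#' @param free logical mask over `(coef, log_alpha)`.
#' @return a wavefunction object.
#' @export
radial_poly_wavefunction <- function(coef, alpha = 1, angular = c("s", "pz"),
                                     free = NULL) {
  angular <- match.arg(angular)
  stopifnot(alpha > 0, length(coef) >= 1)
  theta <- c(coef, log(alpha))
  names(theta) <- c(paste0("c", seq_along(coef) - 1L), "log_alpha")
  if (is.null(free)) free <- rep(TRUE, length(theta))
  structure(
    list(theta = theta, free = free, K = length(coef) - 1L, angular = angular),
    class = c("radial_poly_wavefunction", "wavefunction")
  )
}

.rp_parts <- function(wf, X) {
  r <- sqrt(rowSums(X[, 1:3, drop = FALSE]^2))
  coef <- wf$theta[seq_len(wf$K + 1L)]
  alpha <- exp(wf$theta[["log_alpha"]])
  P <- .polyval(coef, r)
  d1 <- .polyderiv(coef)
  Pp <- .polyval(d1, r)
  Ppp <- .polyval(.polyderiv(d1), r)
  list(r = r, alpha = alpha, P = P, Pp = Pp, Ppp = Ppp)
}

#' @export
psi_eval.radial_poly_wavefunction <- function(wf, X) {
  p <- .rp_parts(wf, X)
  la <- ifelse(p$P == 0, -Inf, log(abs(p$P)) - p$alpha * p$r)
  sg <- sign(p$P)
  if (wf$angular == "pz") {
    z <- X[, 3L]
    sg <- sg * sign(z)
    la <- la + ifelse(z == 0, -Inf, log(abs(z)))
  }
  list(sign = sg, logabs = la)
}

#' @export
psi_grad.radial_poly_wavefunction <- function(wf, X) {
  p <- .rp_parts(wf, X)
  fr <- p$Pp / p$P - p$alpha     # d ln|P e^-ar| / dr
  G <- X[, 1:3, drop = FALSE] * (fr / p$r)
  if (wf$angular == "pz") G[, 3L] <- G[, 3L] + 1 / X[, 3L]
  G
}

#' @export
psi_lap.radial_poly_wavefunction <- function(wf, X) {
  p <- .rp_parts(wf, X)
  fr <- p$Pp / p$P - p$alpha
  frr <- p$Ppp / p$P - (p$Pp / p$P)^2
  lap <- frr + 2 * fr / p$r
  if (wf$angular == "pz") lap <- lap - 1 / X[, 3L]^2
  lap
}

#' @export
psi_pgrad.radial_poly_wavefunction <- function(wf, X) {
  p <- .rp_parts(wf, X)
  G <- cbind(
    vapply(0:wf$K, function(k) p$r^k / p$P, numeric(length(p$r))),
    -p$alpha * p$r    # d/d log_alpha
  )
  colnames(G) <- names(wf$theta)
  .mask_pgrad(wf, G)
}

#' Exact hydrogenic eigenstate
#'
#' Normalized hydrogen-atom states for nuclear charge `Z`, as frozen
#' [radial_poly_wavefunction()]s: `"1s"`, `"2s"` or `"2pz"`. Exact energies
#' `-Z^2/2` and `-Z^2/8`.
#'
#' @param label one of `"1s"`, `"2s"`, `"2pz"`.
#' @param Z nuclear charge.
#' @export
hydrogenic_state <- function(label = c("1s", "2s", "2pz"), Z = 1) {
  label <- match.arg(label)
  wf <- switch(label,
    "1s" = radial_poly_wavefunction(Z^1.5 / sqrt(pi), alpha = Z),
    "2s" = radial_poly_wavefunction(
      Z^1.5 / (4 * sqrt(2 * pi)) * c(2, -Z), alpha = Z / 2),
    "2pz" = radial_poly_wavefunction(
      Z^2.5 / (4 * sqrt(2 * pi)), alpha = Z / 2, angular = "pz")
  )
  wf$free[] <- FALSE
  wf
}

# ---- infinite box eigenstates ----------------------------------------------

#' Exact particle-in-a-box eigenstate (1D)
#'
#' `psi_n(x) = sqrt(2/L) sin(n pi x / L)` on `[0, L]`, zero outside. Exact
#' energy `n^2 pi^2 / (2 L^2)` (1-based `n`). Frozen.
#'
#' @param n quantum number (>= 1).
#' @param L box length.
#' @export
box_eigenstate <- function(n, L = 1) {
  stopifnot(n >= 1, L > 0)
  structure(
    list(n = as.integer(n), L = L, theta = numeric(0), free = logical(0)),
    class = c("box_wavefunction", "wavefunction")
  )
}

#' @export
psi_eval.box_wavefunction <- function(wf, X) {
  x <- X[, 1L]
  k <- wf$n * pi / wf$L
  v <- sqrt(2 / wf$L) * sin(k * x)
  v[x < 0 | x > wf$L] <- 0
  list(sign = sign(v), logabs = ifelse(v == 0, -Inf, log(abs(v))))
}

#' @export
psi_grad.box_wavefunction <- function(wf, X) {
  x <- X[, 1L]
  k <- wf$n * pi / wf$L
  g <- k / tan(k * x)
  g[x < 0 | x > wf$L] <- NaN
  matrix(g, ncol = 1L)
}

#' @export
psi_lap.box_wavefunction <- function(wf, X) {
  x <- X[, 1L]
  k <- wf$n * pi / wf$L
  l <- -k^2 / sin(k * x)^2
  l[x < 0 | x > wf$L] <- NaN
  l
}

#' @export
psi_pgrad.box_wavefunction <- function(wf, X) matrix(0, nrow(X), 0)

# ---- spline wrapper around tabulated eigenfunctions ------------------------

#' Wavefunction interpolated from grid values (1D)
#'
#' Wraps a tabulated function (typically a grid-eigensolver eigenvector)
#' into the wavefunction contract via a natural cubic spline. Frozen.
#'
#' @param x grid nodes (increasing).
#' @param y function values at the nodes.
#' @export
grid_wavefunction <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  f <- stats::splinefun(x, y, method = "natural")
  structure(
    list(f = f, range = range(x), theta = numeric(0), free = logical(0)),
    class = c("grid_wavefunction", "wavefunction")
  )
}

#' @export
psi_eval.grid_wavefunction <- function(wf, X) {
  v <- wf$f(X[, 1L])
  v[X[, 1L] < wf$range[1] | X[, 1L] > wf$range[2]] <- 0
  list(sign = sign(v), logabs = ifelse(v == 0, -Inf, log(abs(v))))
}

#' @export
psi_grad.grid_wavefunction <- function(wf, X) {
  x <- X[, 1L]
  matrix(wf$f(x, deriv = 1L) / wf$f(x), ncol = 1L)
}

#' @export
psi_lap.grid_wavefunction <- function(wf, X) {
  x <- X[, 1L]
  v <- wf$f(x)
  wf$f(x, deriv = 2L) / v - (wf$f(x, deriv = 1L) / v)^2
}

#' @export
psi_pgrad.grid_wavefunction <- function(wf, X) matrix(0, nrow(X), 0)
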