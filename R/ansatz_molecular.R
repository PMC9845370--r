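# Molecular trial wavefunction: fixed cusp envelope x trainable Jastrow x
# sum of backflow-dressed Slater determinant pairs, evaluated in sign/log
# form with exact analytic coordinate and parameter derivatives.
#
#   psi(r) = exp(gamma(r) + J(r)) * sum_p c_p det[phi~_up] det[phi~_down]
#   phi~_{mu i}(r) = phi_mu(r_i) * f^m_{mu i}(r) + f^a_{mu i}(r)
#
# gamma enforces the Kato cusp conditions (electron-nucleus slope -Z;
# electron-electron slope 1/2 opposite spin, 1/4 same spin) and is not
# trainable. J is a sum of scalar tanh networks over cusp-neutral pair
# features, symmetric under like-spin exchange. The backflow heads map
# permutation-equivariant per-electron features (electron-nucleus distances
# plus pooled same/opposite-spin pair features) to one multiplicative and
# one additive dressing per orbital; at initialization f^m = 1, f^a = 0, so
# the fresh ansatz is exactly its determinant baseline.

# ---- feature maps ----------------------------------------------------------

# envelope feature: u(d) = d/(1 + b d); unit slope at coalescence, saturates
# at 1/b so the cusp correction stays local (range ~ 1/b bohr)
.f_u <- function(d, b = 1) d / (1 + b * d)
.f_u1 <- function(d, b = 1) 1 / (1 + b * d)^2
.f_u2 <- function(d, b = 1) -2 * b / (1 + b * d)^3

# cusp-neutral feature: s(d) = d^2/(1+d); zero slope at coalescence
.f_s <- function(d) d^2 / (1 + d)
.f_s1 <- function(d) (d^2 + 2 * d) / (1 + d)^2
.f_s2 <- function(d) 2 / (1 + d)^3

# ---- Gaussian / Slater basis functions -------------------------------------

#' Analytic basis function for molecular orbitals
#'
#' Primitive basis functions with exact first and second derivatives:
#' `"gauss_s"` `exp(-a q^2)`, `"gauss_px/py/pz"` `x_q exp(-a q^2)`, and
#' `"slater_s"` `exp(-z q)` (`q` the distance to `center`).
#'
#' @param type basis function type.
#' @param center length-3 center (bohr).
#' @param exponent positive exponent.
#' @export
basis_function <- function(type = c("gauss_s", "gauss_px", "gauss_py",
                                    "gauss_pz", "slater_s"),
                           center = c(0, 0, 0), exponent = 1) {
  type <- match.arg(type)
  stopifnot(exponent > 0, length(center) == 3)
  structure(list(type = type, center = as.numeric(center),
                 exponent = exponent),
            class = "basis_function")
}

# evaluate value, gradient (3) and diagonal second derivatives (3) at a
# single point r (length 3)
.basis_eval <- function(bf, r) {
  q <- r - bf$center
  a <- bf$exponent
  if (bf$type == "slater_s") {
    d <- sqrt(sum(q^2))
    v <- exp(-a * d)
    g <- -a * q / d * v
    h <- v * (a^2 * q^2 / d^2 - a * (1 / d - q^2 / d^3))
    return(list(v = v, g = g, h = h))
  }
  e <- exp(-a * sum(q^2))
  if (bf$type == "gauss_s") {
    return(list(v = e, g = -2 * a * q * e,
                h = (-2 * a + 4 * a^2 * q^2) * e))
  }
  ax <- switch(bf$type, gauss_px = 1L, gauss_py = 2L, gauss_pz = 3L)
  x <- q[ax]
  v <- x * e
  g <- -2 * a * q * v
  g[ax] <- e * (1 - 2 * a * x^2)
  h <- (-2 * a + 4 * a^2 * q^2) * v
  h[ax] <- e * (-6 * a * x + 4 * a^2 * x^3)
  list(v = v, g = g, h = h)
}

# ---- constructor -----------------------------------------------------------

#' Slater-Jastrow-backflow molecular ansatz
#'
#' Builds the full trainable molecular trial wavefunction. Determinants are
#' specified as lists of occupied orbital indices per spin channel; the
#' orbitals are linear combinations of `basis` with coefficient matrix
#' `orb_coefs` (orbitals x basis functions, trainable). Jastrow and
#' backflow are small tanh networks (zero-initialized output layers) over
#' permutation-invariant distance features. Set `jastrow`/`backflow` to
#' `FALSE` for the bare cusped determinant expansion.
#'
#' @param system a `molecular_system`.
#' @param basis list of [basis_function()]s.
#' @param orb_coefs orbital coefficient matrix (n_orbitals x n_basis), full
#'   row rank at initialization.
#' @param dets list of determinants, each `list(up = idx, down = idx)` with
#'   `length(up) == n_up`, `length(down) == n_down`.
#' @param det_coefs determinant coefficients `c_p`.
#' @param jastrow,backflow include the trainable components?
#' @param width hidden width of the tanh networks.
#' @param seed deterministic weight-initialization seed.
#' @param cusp include the fixed cusp envelope `gamma`?
#' @param cusp_range locality parameter `b` of the envelope feature
#'   `d/(1 + b d)`: the coalescence slopes are exact for any `b`, and the
#'   correction saturates within ~`1/b` bohr so the baseline orbitals are
#'   left essentially untouched outside the coalescence regions.
#' @param same_spin_cusp include the 1/4 same-spin pair slope in `gamma`?
#' @param trainable named logical list over groups `jastrow`, `backflow`,
#'   `orbitals`, `dets` (fixed-spin mode freezes `dets`).
#' @return a wavefunction object of class `slater_jastrow_wavefunction`.
#' @export
slater_jastrow_wavefunction <- function(system, basis, orb_coefs, dets,
                                        det_coefs = rep(1, length(dets)),
                                        jastrow = TRUE, backflow = TRUE,
                                        width = 8L, seed = 1L,
                                        cusp = TRUE, cusp_range = 8,
                                        same_spin_cusp = TRUE,
                                        trainable = list()) {
  stopifnot(inherits(system, "molecular_system"))
  orb_coefs <- as.matrix(orb_coefs)
  n_orb <- nrow(orb_coefs)
  stopifnot(ncol(orb_coefs) == length(basis),
            length(det_coefs) == length(dets), length(dets) >= 1)
  if (qr(orb_coefs)$rank < n_orb) {
    stop("orbital coefficient matrix must have full row rank")
  }
  for (p in dets) {
    stopifnot(length(p$up) == system$n_up, length(p$down) == system$n_down,
              all(c(p$up, p$down) >= 1), all(c(p$up, p$down) <= n_orb))
  }
  tr <- utils::modifyList(
    list(jastrow = TRUE, backflow = TRUE, orbitals = TRUE, dets = TRUE),
    trainable
  )
  M <- nrow(system$positions)
  elems <- sort(unique(system$charges))
  jnets <- NULL
  if (isTRUE(jastrow)) {
    jnets <- list(same = scalar_mlp(width, seed = derive_seed(seed, 1L)),
                  opp = scalar_mlp(width, seed = derive_seed(seed, 2L)),
                  en = stats::setNames(
                    lapply(seq_along(elems), function(k) {
                      scalar_mlp(width, seed = derive_seed(seed, 10L + k))
                    }), as.character(elems)))
  }
  bnets <- NULL
  if (isTRUE(backflow)) {
    d_in <- M + 2L
    bnets <- list(up = vector_mlp(d_in, 2L * n_orb, width,
                                  seed = derive_seed(seed, 3L)),
                  down = vector_mlp(d_in, 2L * n_orb, width,
                                    seed = derive_seed(seed, 4L)))
  }
  wf <- structure(
    list(system = system, basis = basis, orb_coefs = orb_coefs,
         dets = dets, det_coefs = as.numeric(det_coefs),
         jnets = jnets, bnets = bnets,
         cusp = isTRUE(cusp), cusp_range = cusp_range,
         same_spin_cusp = isTRUE(same_spin_cusp),
         elems = elems, trainable = tr),
    class = c("slater_jastrow_wavefunction", "wavefunction")
  )
  .sj_repack(wf)
}

# (re)build the packed parameter vector and free mask from the components
.sj_repack <- function(wf) {
  theta <- numeric(0); free <- logical(0)
  add <- function(v, nm, trn) {
    theta <<- c(theta, stats::setNames(v, paste0(nm, seq_along(v))))
    free <<- c(free, rep(trn, length(v)))
  }
  if (!is.null(wf$jnets)) {
    add(.smlp_pack(wf$jnets$same), "j.same.", wf$trainable$jastrow)
    add(.smlp_pack(wf$jnets$opp), "j.opp.", wf$trainable$jastrow)
    for (z in names(wf$jnets$en)) {
      add(.smlp_pack(wf$jnets$en[[z]]), paste0("j.en", z, "."),
          wf$trainable$jastrow)
    }
  }
  if (!is.null(wf$bnets)) {
    add(.vmlp_pack(wf$bnets$up), "bf.up.", wf$trainable$backflow)
    add(.vmlp_pack(wf$bnets$down), "bf.dn.", wf$trainable$backflow)
  }
  add(as.vector(wf$orb_coefs), "oc.", wf$trainable$orbitals)
  add(wf$det_coefs, "dc.", wf$trainable$dets)
  wf$theta <- theta
  wf$free <- free
  wf
}

#' @export
wf_set_params.slater_jastrow_wavefunction <- function(wf, theta) {
  stopifnot(length(theta) == length(wf$theta))
  theta <- stats::setNames(as.numeric(theta), names(wf$theta))
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  if (!is.null(wf$jnets)) {
    wf$jnets$same <- .smlp_unpack(wf$jnets$same, take(.smlp_npar(wf$jnets$same)))
    wf$jnets$opp <- .smlp_unpack(wf$jnets$opp, take(.smlp_npar(wf$jnets$opp)))
    for (z in names(wf$jnets$en)) {
      wf$jnets$en[[z]] <- .smlp_unpack(wf$jnets$en[[z]],
                                       take(.smlp_npar(wf$jnets$en[[z]])))
    }
  }
  if (!is.null(wf$bnets)) {
    wf$bnets$up <- .vmlp_unpack(wf$bnets$up, take(.vmlp_npar(wf$bnets$up)))
    wf$bnets$down <- .vmlp_unpack(wf$bnets$down, take(.vmlp_npar(wf$bnets$down)))
  }
  wf$orb_coefs <- matrix(take(length(wf$orb_coefs)), nrow(wf$orb_coefs))
  wf$det_coefs <- as.numeric(take(length(wf$det_coefs)))
  wf$theta <- theta
  wf
}

# ---- cusp envelope ---------------------------------------------------------

#' Fixed cusp envelope (log-amplitude)
#'
#' The non-trainable log-domain envelope enforcing the Kato coalescence
#' conditions: radial slope `-Z_I` of `ln|psi|` at each nucleus, pair slope
#' `+1/2` for opposite-spin and `+1/4` for same-spin electron pairs
#' (`gamma = sum -Z u(r_iI) + sum c_ij u(r_ij)`, `u(d) = d/(1+d)`).
#'
#' @param system a `molecular_system`.
#' @param conf configuration matrix or flat vector.
#' @param same_spin_cusp include the same-spin 1/4 slope?
#' @param range locality parameter of the envelope feature (see
#'   [slater_jastrow_wavefunction()]).
#' @return numeric vector of `gamma` values, one per walker.
#' @export
cusp_envelope <- function(system, conf, same_spin_cusp = TRUE, range = 8) {
  X <- as_conf_matrix(conf, system)
  N <- n_particles(system)
  g <- numeric(nrow(X))
  for (i in seq_len(N)) {
    for (I in seq_along(system$charges)) {
      d <- .dist_to_point(X, i, 3L, system$positions[I, ])
      g <- g - system$charges[I] * .f_u(d, range)
    }
  }
  if (N > 1) {
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      same <- (i <= system$n_up) == (j <= system$n_up)
      cc <- if (same) {
        if (same_spin_cusp) 0.25 else 0
      } else 0.5
      if (cc != 0) g <- g + cc * .f_u(.dist_between(X, i, j, 3L), range)
    }
  }
  g
}

# ---- geometry scaffolding for one walker -----------------------------------

# distances, unit vectors and their derivatives for one configuration
.sj_geom <- function(wf, x) {
  sys <- wf$system
  N <- n_particles(sys)
  M <- nrow(sys$positions)
  Re <- matrix(x, N, 3, byrow = TRUE)
  d_en <- matrix(0, N, M)
  e_en <- array(0, c(N, M, 3))
  for (i in seq_len(N)) for (I in seq_len(M)) {
    q <- Re[i, ] - sys$positions[I, ]
    d <- sqrt(sum(q^2))
    d_en[i, I] <- d
    e_en[i, I, ] <- q / d
  }
  d_ee <- matrix(0, N, N)
  e_ee <- array(0, c(N, N, 3))   # unit vector from j toward i in row [i,j,]
  if (N > 1) {
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      q <- Re[i, ] - Re[j, ]
      d <- sqrt(sum(q^2))
      d_ee[i, j] <- d_ee[j, i] <- d
      e_ee[i, j, ] <- q / d
      e_ee[j, i, ] <- -q / d
    }
  }
  spin <- rep(c(1L, 2L), c(sys$n_up, sys$n_down))
  list(N = N, M = M, Re = Re, d_en = d_en, e_en = e_en,
       d_ee = d_ee, e_ee = e_ee, spin = spin)
}

# gamma (cusp envelope) value, gradient (N x 3), diagonal Hessian (N x 3)
.sj_gamma <- function(wf, gm) {
  sys <- wf$system
  b <- wf$cusp_range %||% 8
  val <- 0
  G <- matrix(0, gm$N, 3)
  H <- matrix(0, gm$N, 3)
  for (i in seq_len(gm$N)) {
    for (I in seq_len(gm$M)) {
      d <- gm$d_en[i, I]; e <- gm$e_en[i, I, ]; Z <- sys$charges[I]
      val <- val - Z * .f_u(d, b)
      G[i, ] <- G[i, ] - Z * .f_u1(d, b) * e
      H[i, ] <- H[i, ] - Z * (.f_u2(d, b) * e^2 + .f_u1(d, b) * (1 - e^2) / d)
    }
  }
  if (gm$N > 1) {
    for (i in seq_len(gm$N - 1)) for (j in (i + 1):gm$N) {
      same <- gm$spin[i] == gm$spin[j]
      cc <- if (same) {
        if (wf$same_spin_cusp) 0.25 else 0
      } else 0.5
      if (cc == 0) next
      d <- gm$d_ee[i, j]
      val <- val + cc * .f_u(d, b)
      for (k in c(i, j)) {
        e <- gm$e_ee[k, if (k == i) j else i, ]
        G[k, ] <- G[k, ] + cc * .f_u1(d, b) * e
        H[k, ] <- H[k, ] + cc * (.f_u2(d, b) * e^2 + .f_u1(d, b) * (1 - e^2) / d)
      }
    }
  }
  list(value = val, G = G, H = H)
}

# Jastrow value, gradient, diagonal Hessian; optionally weight gradients
.sj_jastrow <- function(wf, gm, want_pgrad = FALSE) {
  val <- 0
  G <- matrix(0, gm$N, 3)
  H <- matrix(0, gm$N, 3)
  pg <- list()
  add_term <- function(net, d, touch) {
    # touch: list of (electron index, unit vector toward the partner)
    s <- .f_s(d)
    fw <- .smlp_forward(net, s)
    sp <- .f_s1(d); spp <- .f_s2(d)
    for (tc in touch) {
      k <- tc$k; e <- tc$e
      G[k, ] <<- G[k, ] + fw$d1 * sp * e
      H[k, ] <<- H[k, ] + fw$d2 * (sp * e)^2 +
        fw$d1 * (spp * e^2 + sp * (1 - e^2) / d)
    }
    list(value = fw$value, s = s, fwd = fw)
  }
  terms <- list(same = list(), opp = list())
  for (z in names(wf$jnets$en)) terms[[paste0("en", z)]] <- list()
  if (gm$N > 1) {
    for (i in seq_len(gm$N - 1)) for (j in (i + 1):gm$N) {
      same <- gm$spin[i] == gm$spin[j]
      net <- if (same) wf$jnets$same else wf$jnets$opp
      tm <- add_term(net, gm$d_ee[i, j],
                     list(list(k = i, e = gm$e_ee[i, j, ]),
                          list(k = j, e = gm$e_ee[j, i, ])))
      val <- val + tm$value
      key <- if (same) "same" else "opp"
      terms[[key]] <- c(terms[[key]], list(tm))
    }
  }
  for (i in seq_len(gm$N)) {
    for (I in seq_len(gm$M)) {
      z <- as.character(wf$system$charges[I])
      tm <- add_term(wf$jnets$en[[z]], gm$d_en[i, I],
                     list(list(k = i, e = gm$e_en[i, I, ])))
      val <- val + tm$value
      terms[[paste0("en", z)]] <- c(terms[[paste0("en", z)]], list(tm))
    }
  }
  if (want_pgrad) {
    grads <- list()
    bp <- function(net, tms) {
      if (!length(tms)) return(numeric(.smlp_npar(net)))
      s <- vapply(tms, `[[`, numeric(1), "s")
      fw <- .smlp_forward(net, s, want_deriv = FALSE)
      .smlp_backprop(net, s, fw, rep(1, length(s)))
    }
    grads$same <- bp(wf$jnets$same, terms$same)
    grads$opp <- bp(wf$jnets$opp, terms$opp)
    for (z in names(wf$jnets$en)) {
      grads[[paste0("en", z)]] <- bp(wf$jnets$en[[z]], terms[[paste0("en", z)]])
    }
    pg <- grads
  }
  list(value = val, G = G, H = H, pgrad = pg)
}

# per-electron backflow features and their coordinate derivatives:
#   t_j = ( u(d_j1), ..., u(d_jM), sum_same s(d_jk), sum_opp s(d_jk) )
# dt[j][[i]] is a 3 x D matrix of dt_j / dx_{i,alpha};
# ht[j][[i]] the matching diagonal second derivatives
.sj_features <- function(wf, gm) {
  N <- gm$N; M <- gm$M
  D <- M + 2L
  tfeat <- matrix(0, N, D)
  dt <- vector("list", N)
  ht <- vector("list", N)
  for (j in seq_len(N)) {
    dt[[j]] <- vector("list", N)
    ht[[j]] <- vector("list", N)
    for (i in seq_len(N)) {
      dt[[j]][[i]] <- matrix(0, 3, D)
      ht[[j]][[i]] <- matrix(0, 3, D)
    }
    for (I in seq_len(M)) {
      d <- gm$d_en[j, I]; e <- gm$e_en[j, I, ]
      tfeat[j, I] <- .f_u(d)
      dt[[j]][[j]][, I] <- .f_u1(d) * e
      ht[[j]][[j]][, I] <- .f_u2(d) * e^2 + .f_u1(d) * (1 - e^2) / d
    }
    for (k in seq_len(N)) {
      if (k == j) next
      col <- if (gm$spin[k] == gm$spin[j]) M + 1L else M + 2L
      d <- gm$d_ee[j, k]
      tfeat[j, col] <- tfeat[j, col] + .f_s(d)
      ejk <- gm$e_ee[j, k, ]   # unit vector at j pointing away from k
      sp <- .f_s1(d); spp <- .f_s2(d)
      curv <- spp * ejk^2 + sp * (1 - ejk^2) / d
      dt[[j]][[j]][, col] <- dt[[j]][[j]][, col] + sp * ejk
      ht[[j]][[j]][, col] <- ht[[j]][[j]][, col] + curv
      dt[[j]][[k]][, col] <- dt[[j]][[k]][, col] - sp * ejk
      ht[[j]][[k]][, col] <- ht[[j]][[k]][, col] + curv
    }
  }
  list(t = tfeat, dt = dt, ht = ht, D = D)
}

# full dressed matrix A (n_orb x N) and its coordinate derivative tensors
.sj_matrix <- function(wf, gm, want_deriv = TRUE, want_bf_detail = FALSE) {
  N <- gm$N
  n_orb <- nrow(wf$orb_coefs)
  # bare orbital values and derivatives at each electron
  Phi <- matrix(0, n_orb, N)
  dPhi <- array(0, c(n_orb, N, 3))
  hPhi <- array(0, c(n_orb, N, 3))
  for (j in seq_len(N)) {
    for (k in seq_along(wf$basis)) {
      be <- .basis_eval(wf$basis[[k]], gm$Re[j, ])
      cmu <- wf$orb_coefs[, k]
      Phi[, j] <- Phi[, j] + cmu * be$v
      for (al in 1:3) {
        dPhi[, j, al] <- dPhi[, j, al] + cmu * be$g[al]
        hPhi[, j, al] <- hPhi[, j, al] + cmu * be$h[al]
      }
    }
  }
  if (is.null(wf$bnets)) {
    A <- Phi
    dA <- hA <- NULL
    if (want_deriv) {
      dA <- array(0, c(n_orb, N, N, 3))
      hA <- array(0, c(n_orb, N, N, 3))
      for (j in seq_len(N)) for (al in 1:3) {
        dA[, j, j, al] <- dPhi[, j, al]
        hA[, j, j, al] <- hPhi[, j, al]
      }
    }
    return(list(A = A, dA = dA, hA = hA, Phi = Phi, ft = NULL, bf = NULL))
  }
  ft <- .sj_features(wf, gm)
  A <- matrix(0, n_orb, N)
  dA <- hA <- NULL
  if (want_deriv) {
    dA <- array(0, c(n_orb, N, N, 3))
    hA <- array(0, c(n_orb, N, N, 3))
  }
  bf <- vector("list", N)
  for (j in seq_len(N)) {
    net <- if (gm$spin[j] == 1L) wf$bnets$up else wf$bnets$down
    fw <- .vmlp_forward(net, ft$t[j, ], want_jac = want_deriv,
                        want_hess = want_deriv)
    m <- fw$value[seq_len(n_orb)]
    a <- fw$value[n_orb + seq_len(n_orb)]
    A[, j] <- Phi[, j] * (1 + m) + a
    bf[[j]] <- list(fwd = fw, m = m, a = a, net_id = gm$spin[j])
    if (want_deriv) {
      Jm <- fw$jac[seq_len(n_orb), , drop = FALSE]        # dm/dt
      Ja <- fw$jac[n_orb + seq_len(n_orb), , drop = FALSE]
      for (i in seq_len(N)) {
        dtj <- ft$dt[[j]][[i]]   # 3 x D
        htj <- ft$ht[[j]][[i]]
        if (all(dtj == 0) && all(htj == 0) && i != j) next
        for (al in 1:3) {
          tv <- dtj[al, ]; hv <- htj[al, ]
          dm <- drop(Jm %*% tv); da <- drop(Ja %*% tv)
          # quadratic Hessian terms per orbital output
          qm <- vapply(seq_len(n_orb), function(o) {
            drop(tv %*% fw$hess[[o]] %*% tv)
          }, numeric(1))
          qa <- vapply(seq_len(n_orb), function(o) {
            drop(tv %*% fw$hess[[n_orb + o]] %*% tv)
          }, numeric(1))
          d2m <- qm + drop(Jm %*% hv)
          d2a <- qa + drop(Ja %*% hv)
          dA[, j, i, al] <- dA[, j, i, al] + Phi[, j] * dm + da
          hA[, j, i, al] <- hA[, j, i, al] + Phi[, j] * d2m + d2a
          if (i == j) {
            dA[, j, i, al] <- dA[, j, i, al] + dPhi[, j, al] * (1 + m)
            hA[, j, i, al] <- hA[, j, i, al] + hPhi[, j, al] * (1 + m) +
              2 * dPhi[, j, al] * dm
          }
        }
      }
    }
  }
  list(A = A, dA = dA, hA = hA, Phi = Phi, ft = ft, bf = bf)
}

# determinant part for one configuration: value in sign/log form, per-
# coordinate gradient and diagonal Hessian of ln|det sum|, and the entry
# cotangent E_cot[mu, j] = sum_p w_p (A_p^{-1})[col(j), row(mu)] for
# parameter backprop
.sj_det <- function(wf, gm, mat, want_deriv = TRUE, want_cot = FALSE) {
  sys <- wf$system
  N <- gm$N
  n_orb <- nrow(wf$orb_coefs)
  up_cols <- seq_len(sys$n_up)
  dn_cols <- if (sys$n_down > 0) sys$n_up + seq_len(sys$n_down) else integer(0)
  P <- length(wf$dets)
  sgn <- numeric(P); lg <- numeric(P)
  blocks <- vector("list", P)
  for (p in seq_len(P)) {
    occ <- wf$dets[[p]]
    bl <- list()
    s_p <- sign(wf$det_coefs[p]); l_p <- log(abs(wf$det_coefs[p]))
    for (ch in c("up", "down")) {
      cols <- if (ch == "up") up_cols else dn_cols
      if (!length(cols)) next
      Ab <- mat$A[occ[[ch]], cols, drop = FALSE]
      dd <- determinant(Ab, logarithm = TRUE)
      s_p <- s_p * dd$sign
      l_p <- l_p + as.numeric(dd$modulus)
      bl[[ch]] <- list(Ab = Ab, occ = occ[[ch]], cols = cols,
                       inv = if (dd$sign != 0) solve(Ab) else NULL,
                       sign = dd$sign)
    }
    sgn[p] <- s_p; lg[p] <- l_p
    blocks[[p]] <- bl
  }
  tot <- signed_logsumexp(sgn, lg)
  if (tot$sign == 0) {
    return(list(sign = 0, logabs = -Inf))
  }
  w_p <- sgn * exp(lg - tot$logabs) * tot$sign
  out <- list(sign = tot$sign, logabs = tot$logabs, w_p = w_p, blocks = blocks)
  if (want_deriv) {
    G <- matrix(0, N, 3)        # d ln|det sum| / dx
    Hq <- matrix(0, N, 3)       # sum_p w_p (L + G_p^2) accumulator
    for (p in seq_len(P)) {
      if (w_p[p] == 0 || is.null(blocks[[p]])) next
      for (i in seq_len(N)) for (al in 1:3) {
        Gp <- 0; Lp <- 0
        for (ch in names(blocks[[p]])) {
          bl <- blocks[[p]][[ch]]
          if (is.null(bl$inv)) next
          B1 <- mat$dA[bl$occ, bl$cols, i, al, drop = FALSE]
          dim(B1) <- c(length(bl$occ), length(bl$cols))
          B2 <- mat$hA[bl$occ, bl$cols, i, al, drop = FALSE]
          dim(B2) <- c(length(bl$occ), length(bl$cols))
          AiB <- bl$inv %*% B1
          Gp <- Gp + sum(diag(AiB))
          Lp <- Lp + sum(diag(bl$inv %*% B2)) - sum(AiB * t(AiB))
        }
        G[i, al] <- G[i, al] + w_p[p] * Gp
        Hq[i, al] <- Hq[i, al] + w_p[p] * (Lp + Gp^2)
      }
    }
    out$G <- G
    out$H <- Hq - G^2           # diagonal Hessian of ln|det sum|
  }
  if (want_cot) {
    Ecot <- matrix(0, n_orb, N)
    for (p in seq_len(P)) {
      if (w_p[p] == 0) next
      for (ch in names(blocks[[p]])) {
        bl <- blocks[[p]][[ch]]
        if (is.null(bl$inv)) next
        for (r in seq_along(bl$occ)) for (cc in seq_along(bl$cols)) {
          Ecot[bl$occ[r], bl$cols[cc]] <-
            Ecot[bl$occ[r], bl$cols[cc]] + w_p[p] * bl$inv[cc, r]
        }
      }
    }
    out$Ecot <- Ecot
  }
  out
}

# ---- wavefunction contract methods -----------------------------------------

.sj_eval_one <- function(wf, x, want_deriv = FALSE) {
  gm <- .sj_geom(wf, x)
  mat <- .sj_matrix(wf, gm, want_deriv = want_deriv)
  det_part <- .sj_det(wf, gm, mat, want_deriv = want_deriv)
  if (det_part$sign == 0) {
    return(list(sign = 0, logabs = -Inf,
                G = matrix(NaN, gm$N, 3), H = matrix(NaN, gm$N, 3)))
  }
  val <- det_part$logabs
  G <- if (want_deriv) det_part$G else NULL
  H <- if (want_deriv) det_part$H else NULL
  if (wf$cusp) {
    ga <- .sj_gamma(wf, gm)
    val <- val + ga$value
    if (want_deriv) { G <- G + ga$G; H <- H + ga$H }
  }
  if (!is.null(wf$jnets)) {
    jj <- .sj_jastrow(wf, gm)
    val <- val + jj$value
    if (want_deriv) { G <- G + jj$G; H <- H + jj$H }
  }
  list(sign = det_part$sign, logabs = val, G = G, H = H)
}

#' @export
psi_eval.slater_jastrow_wavefunction <- function(wf, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  B <- nrow(X)
  sg <- numeric(B); la <- numeric(B)
  for (b in seq_len(B)) {
    e <- .sj_eval_one(wf, X[b, ])
    sg[b] <- e$sign; la[b] <- e$logabs
  }
  list(sign = sg, logabs = la)
}

#' @export
psi_grad.slater_jastrow_wavefunction <- function(wf, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  B <- nrow(X)
  G <- matrix(NA_real_, B, ncol(X))
  for (b in seq_len(B)) {
    e <- .sj_eval_one(wf, X[b, ], want_deriv = TRUE)
    G[b, ] <- as.vector(t(e$G))
  }
  G
}

#' @export
psi_lap.slater_jastrow_wavefunction <- function(wf, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  B <- nrow(X)
  l <- numeric(B)
  for (b in seq_len(B)) {
    e <- .sj_eval_one(wf, X[b, ], want_deriv = TRUE)
    l[b] <- sum(e$H)
  }
  l
}

#' @export
psi_pgrad.slater_jastrow_wavefunction <- function(wf, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  B <- nrow(X)
  G <- matrix(0, B, length(wf$theta))
  colnames(G) <- names(wf$theta)
  n_orb <- nrow(wf$orb_coefs)
  for (b in seq_len(B)) {
    gm <- .sj_geom(wf, X[b, ])
    mat <- .sj_matrix(wf, gm, want_deriv = FALSE)
    det_part <- .sj_det(wf, gm, mat, want_deriv = FALSE, want_cot = TRUE)
    if (det_part$sign == 0) { G[b, ] <- NaN; next }
    g <- numeric(0)
    if (!is.null(wf$jnets)) {
      jj <- .sj_jastrow(wf, gm, want_pgrad = TRUE)
      g <- c(g, jj$pgrad$same, jj$pgrad$opp)
      for (z in names(wf$jnets$en)) g <- c(g, jj$pgrad[[paste0("en", z)]])
    }
    if (!is.null(wf$bnets)) {
      gup <- numeric(.vmlp_npar(wf$bnets$up))
      gdn <- numeric(.vmlp_npar(wf$bnets$down))
      for (j in seq_len(gm$N)) {
        cot_m <- det_part$Ecot[, j] * mat$Phi[, j]
        cot_a <- det_part$Ecot[, j]
        cot <- c(cot_m, cot_a)
        if (all(cot == 0)) next
        if (gm$spin[j] == 1L) {
          gup <- gup + .vmlp_backprop(wf$bnets$up, mat$ft$t[j, ],
                                      mat$bf[[j]]$fwd, cot)
        } else {
          gdn <- gdn + .vmlp_backprop(wf$bnets$down, mat$ft$t[j, ],
                                      mat$bf[[j]]$fwd, cot)
        }
      }
      g <- c(g, gup, gdn)
    }
    # orbital coefficients: dA[mu,j]/dc[mu,k] = basis_k(r_j) * (1 + m_j[mu])
    goc <- matrix(0, n_orb, length(wf$basis))
    basis_vals <- vapply(seq_along(wf$basis), function(k) {
      vapply(seq_len(gm$N), function(j) {
        .basis_eval(wf$basis[[k]], gm$Re[j, ])$v
      }, numeric(1))
    }, numeric(gm$N))   # N x n_basis
    for (j in seq_len(gm$N)) {
      mult <- if (!is.null(mat$bf)) 1 + mat$bf[[j]]$m else rep(1, n_orb)
      goc <- goc + (det_part$Ecot[, j] * mult) %o% basis_vals[j, ]
    }
    g <- c(g, as.vector(goc))
    # determinant coefficients: d ln psi / d c_p
    P <- length(wf$dets)
    gdc <- numeric(P)
    for (p in seq_len(P)) {
      if (wf$det_coefs[p] != 0) {
        gdc[p] <- det_part$w_p[p] / wf$det_coefs[p]
      }
    }
    g <- c(g, gdc)
    G[b, ] <- g
  }
  .mask_pgrad(wf, G)
}

#' Backflow-dressed orbital matrices
#'
#' Returns the generalized orbital matrix `phi~_{mu i}` per spin channel for
#' a single configuration: `phi~ = phi_mu(r_i) f^m + f^a`. With the
#' backflow disabled (or freshly initialized) this equals the bare orbital
#' matrix. Columns permute with like-spin electrons (equivariance).
#'
#' @param wf a `slater_jastrow_wavefunction`.
#' @param conf a single configuration (flat vector or 1-row matrix).
#' @return list with matrices `up` (n_orb x n_up) and `down`.
#' @export
dressed_orbitals <- function(wf, conf) {
  x <- if (is.matrix(conf)) conf[1, ] else as.numeric(conf)
  gm <- .sj_geom(wf, x)
  mat <- .sj_matrix(wf, gm, want_deriv = FALSE)
  sys <- wf$system
  list(up = mat$A[, seq_len(sys$n_up), drop = FALSE],
       down = if (sys$n_down > 0) {
         mat$A[, sys$n_up + seq_len(sys$n_down), drop = FALSE]
       } else matrix(0, nrow(mat$A), 0))
}
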