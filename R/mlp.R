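# Small tanh networks with hand-coded forward and backward passes. These
# are the trainable Jastrow / backflow components: every derivative used in
# the local energy (first and second derivatives with respect to inputs)
# and in the optimizer (gradients with respect to weights) is analytic.

#' Scalar tanh network (2 hidden layers)
#'
#' Maps a scalar feature to a scalar output through two tanh hidden layers.
#' The output layer initializes to zero so freshly built Jastrow/backflow
#' components leave the ansatz exactly at its baseline. Carries closed-form
#' first and second input-derivatives and weight gradients.
#'
#' @param width hidden width.
#' @param seed seed for the (deterministic) weight initialization.
#' @return object of class `scalar_mlp`.
#' @keywords internal
scalar_mlp <- function(width = 8L, seed = 1L) {
  res <- with_rng_state(NULL, {
    set.seed(seed)
    list(
      W1 = stats::rnorm(width, sd = 1), b1 = stats::rnorm(width, sd = 0.5),
      W2 = matrix(stats::rnorm(width^2, sd = 1 / sqrt(width)), width, width),
      b2 = stats::rnorm(width, sd = 0.5),
      W3 = numeric(width), b3 = 0
    )
  })
  structure(c(res$value, list(width = width)), class = "scalar_mlp")
}

# number of trainable parameters
.smlp_npar <- function(net) with(net, length(W1) + length(b1) + length(W2) +
                                   length(b2) + length(W3) + 1L)

.smlp_pack <- function(net) {
  c(net$W1, net$b1, as.vector(net$W2), net$b2, net$W3, net$b3)
}

.smlp_unpack <- function(net, theta) {
  w <- net$width
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  net$W1 <- take(w); net$b1 <- take(w)
  net$W2 <- matrix(take(w * w), w, w)
  net$b2 <- take(w); net$W3 <- take(w); net$b3 <- take(1L)
  net
}

# forward pass over a vector of scalar inputs; returns value and the
# first/second input derivatives, plus the hidden activations for backprop
.smlp_forward <- function(net, s, want_deriv = TRUE) {
  B <- length(s)
  Z1 <- outer(s, net$W1) + matrix(net$b1, B, net$width, byrow = TRUE)
  H1 <- tanh(Z1)
  Z2 <- H1 %*% net$W2 + matrix(net$b2, B, net$width, byrow = TRUE)
  H2 <- tanh(Z2)
  out <- drop(H2 %*% net$W3) + net$b3
  res <- list(value = out, H1 = H1, H2 = H2)
  if (want_deriv) {
    D1 <- (1 - H1^2) * matrix(net$W1, B, net$width, byrow = TRUE)   # dH1/ds
    S1 <- -2 * H1 * (1 - H1^2) * matrix(net$W1^2, B, net$width, byrow = TRUE)
    Z2p <- D1 %*% net$W2
    Z2pp <- S1 %*% net$W2
    D2 <- (1 - H2^2) * Z2p
    S2 <- -2 * H2 * (1 - H2^2) * Z2p^2 + (1 - H2^2) * Z2pp
    res$d1 <- drop(D2 %*% net$W3)
    res$d2 <- drop(S2 %*% net$W3)
  }
  res
}

# gradient of sum(cot * out) with respect to the packed weights, given the
# forward activations; `cot` is a per-row cotangent
.smlp_backprop <- function(net, s, fwd, cot) {
  H1 <- fwd$H1; H2 <- fwd$H2
  gW3 <- colSums(cot * H2)
  gb3 <- sum(cot)
  delta2 <- (cot * (1 - H2^2)) * matrix(net$W3, length(s), net$width, byrow = TRUE)
  gW2 <- t(H1) %*% delta2
  gb2 <- colSums(delta2)
  delta1 <- (delta2 %*% t(net$W2)) * (1 - H1^2)
  gW1 <- colSums(delta1 * s)
  gb1 <- colSums(delta1)
  c(gW1, gb1, as.vector(gW2), gb2, gW3, gb3)
}

#' Vector-input tanh network (2 hidden layers)
#'
#' Maps a feature vector (dimension `d_in`) to `d_out` outputs; used for the
#' backflow heads. Provides the full input Jacobian and per-output input
#' Hessians (needed for exact Laplacians through pooled many-electron
#' features) and weight gradients. Output layer initialized to zero.
#'
#' @param d_in,d_out input / output dimensions.
#' @param width hidden width.
#' @param seed initialization seed.
#' @return object of class `vector_mlp`.
#' @keywords internal
vector_mlp <- function(d_in, d_out, width = 8L, seed = 1L) {
  res <- with_rng_state(NULL, {
    set.seed(seed)
    list(
      W1 = matrix(stats::rnorm(width * d_in, sd = 1 / sqrt(d_in)), width, d_in),
      b1 = stats::rnorm(width, sd = 0.5),
      W2 = matrix(stats::rnorm(width^2, sd = 1 / sqrt(width)), width, width),
      b2 = stats::rnorm(width, sd = 0.5),
      W3 = matrix(0, d_out, width), b3 = numeric(d_out)
    )
  })
  structure(c(res$value, list(width = width, d_in = d_in, d_out = d_out)),
            class = "vector_mlp")
}

.vmlp_npar <- function(net) {
  with(net, length(W1) + length(b1) + length(W2) + length(b2) +
         length(W3) + length(b3))
}

.vmlp_pack <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2,
    as.vector(net$W3), net$b3)
}

.vmlp_unpack <- function(net, theta) {
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  net$W1 <- matrix(take(length(net$W1)), nrow(net$W1))
  net$b1 <- take(length(net$b1))
  net$W2 <- matrix(take(length(net$W2)), nrow(net$W2))
  net$b2 <- take(length(net$b2))
  net$W3 <- matrix(take(length(net$W3)), nrow(net$W3))
  net$b3 <- take(length(net$b3))
  net
}

# forward for a single feature vector t; optionally Jacobian (d_out x d_in)
# and the list of per-output Hessians (d_in x d_in)
.vmlp_forward <- function(net, t, want_jac = FALSE, want_hess = FALSE) {
  z1 <- drop(net$W1 %*% t) + net$b1
  h1 <- tanh(z1)
  z2 <- drop(net$W2 %*% h1) + net$b2
  h2 <- tanh(z2)
  out <- drop(net$W3 %*% h2) + net$b3
  res <- list(value = out, h1 = h1, h2 = h2)
  if (want_jac || want_hess) {
    J1 <- (1 - h1^2) * net$W1            # width x d_in
    A2 <- net$W2 %*% J1                  # d z2 / d t
    J2 <- (1 - h2^2) * A2
    res$jac <- net$W3 %*% J2             # d_out x d_in
    if (want_hess) {
      # Hessians of h1_k: -2 h1 (1-h1^2) w1_k w1_k'
      # Hessians of h2_k: -2 h2 (1-h2^2) a2_k a2_k' + (1-h2^2) sum_m W2[k,m] H1_m
      H1 <- lapply(seq_along(h1), function(k) {
        -2 * h1[k] * (1 - h1[k]^2) * tcrossprod(net$W1[k, ])
      })
      H2 <- lapply(seq_along(h2), function(k) {
        M <- -2 * h2[k] * (1 - h2[k]^2) * tcrossprod(A2[k, ])
        for (m in seq_along(h1)) {
          if (net$W2[k, m] != 0) M <- M + (1 - h2[k]^2) * net$W2[k, m] * H1[[m]]
        }
        M
      })
      res$hess <- lapply(seq_len(net$d_out), function(o) {
        M <- matrix(0, net$d_in, net$d_in)
        for (k in seq_along(h2)) {
          if (net$W3[o, k] != 0) M <- M + net$W3[o, k] * H2[[k]]
        }
        M
      })
    }
  }
  res
}

# gradient of sum(cot * out) wrt packed weights for one feature vector
.vmlp_backprop <- function(net, t, fwd, cot) {
  h1 <- fwd$h1; h2 <- fwd$h2
  gW3 <- tcrossprod(cot, h2)
  gb3 <- cot
  delta2 <- drop(crossprod(net$W3, cot)) * (1 - h2^2)
  gW2 <- tcrossprod(delta2, h1)
  gb2 <- delta2
  delta1 <- drop(crossprod(net$W2, delta2)) * (1 - h1^2)
  gW1 <- tcrossprod(delta1, t)
  gb1 <- delta1
  c(as.vector(gW1), gb1, as.vector(gW2), gb2, as.vector(gW3), gb3)
}
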