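# Internal numerical helpers shared across modules.

#' Signed log-sum-exp
#'
#' Stable evaluation of `sum(sign * exp(logabs))` returned in sign/log form.
#' Used wherever determinant expansions or linear combinations of
#' wavefunctions are accumulated in the log domain.
#'
#' @param sign integer vector in {-1, 0, 1}.
#' @param logabs numeric vector of log magnitudes (`-Inf` allowed).
#' @return list with elements `sign` and `logabs` of the signed sum.
#' @keywords internal
signed_logsumexp <- function(sign, logabs) {
  keep <- sign != 0 & is.finite(logabs)
  if (!any(keep)) {
    return(list(sign = 0, logabs = -Inf))
  }
  s <- sign[keep]
  l <- logabs[keep]
  m <- max(l)
  tot <- sum(s * exp(l - m))
  if (tot == 0) {
    return(list(sign = 0, logabs = -Inf))
  }
  list(sign = sign(tot), logabs = m + log(abs(tot)))
}

#' Standard error of the mean
#' @keywords internal
se_mean <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

#' Block-jackknife standard error of a statistic of one or two samples
#'
#' Splits each sample into `blocks` contiguous blocks and applies the
#' delete-one-block jackknife. `fun` receives the retained subsets.
#'
#' @keywords internal
jackknife_se <- function(fun, x, y = NULL, blocks = 20L) {
  n <- length(x)
  blocks <- max(2L, min(blocks, n))
  idx <- cut(seq_len(n), blocks, labels = FALSE)
  if (!is.null(y)) {
    idy <- cut(seq_along(y), blocks, labels = FALSE)
  }
  reps <- vapply(seq_len(blocks), function(b) {
    if (is.null(y)) {
      fun(x[idx != b])
    } else {
      fun(x[idx != b], y[idy != b])
    }
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  m <- length(reps)
  if (m < 2L) return(NA_real_)
  sqrt((m - 1) / m * sum((reps - mean(reps))^2))
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L + 13L
}

#' Capture / restore the global RNG state around a block
#'
#' Each walker ensemble owns an RNG state so chains for different states are
#' independent streams and runs are bit-reproducible.
#' @keywords internal
with_rng_state <- function(state, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
  res <- force(expr)
  new_state <- get(".Random.seed", envir = .GlobalEnv)
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  list(value = res, state = new_state)
}

#' Winsorize a vector at median +/- k * mean absolute deviation
#'
#' Stabilization used on local energies along the gradient path only.
#' @keywords internal
winsorize_mad <- function(x, k = 5) {
  med <- stats::median(x)
  mad_mean <- mean(abs(x - med))
  if (!is.finite(mad_mean) || mad_mean == 0) return(x)
  pmin(pmax(x, med - k * mad_mean), med + k * mad_mean)
}

#' Clip a vector to a maximum Euclidean norm
#' @keywords internal
clip_norm <- function(g, max_norm) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(max_norm) && nrm > max_norm && nrm > 0) {
    g * (max_norm / nrm)
  } else {
    g
  }
}

#' Condition constructors used across the package
#' @keywords internal
singular_configuration <- function(conf, msg = "singular configuration: coincident particles") {
  structure(
    class = c("singular_configuration", "error", "condition"),
    list(message = msg, call = sys.call(-1), conf = conf)
  )
}

#' @keywords internal
numerical_breakdown <- function(conf, msg = "numerical breakdown: non-finite derivative") {
  structure(
    class = c("numerical_breakdown", "error", "condition"),
    list(message = msg, call = sys.call(-1), conf = conf)
  )
}
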