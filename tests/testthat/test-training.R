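test_that("penalty identities hold analytically", {
  expect_identical(overlap_penalty(0), 0)
  expect_equal(overlap_penalty(0.5), 1)
  # first-order linearity: deviation bounded by the quadratic remainder
  expect_lt(abs(overlap_penalty(1e-3) - 1e-3), 2 * (1e-3)^2)
  s <- seq(-0.5, 0.5, length.out = 401)
  expect_true(all(abs(overlap_penalty(s) - abs(s)) <= 2 * s^2 + 1e-15))
  s2 <- seq(0, 0.999, length.out = 2000)
  expect_true(all(overlap_penalty(s2) >= s2^2 - 1e-15))
  expect_true(all(diff(overlap_penalty(s2)) >= 0))
  # clamp keeps the loss finite exactly at collapse
  expect_true(is.finite(overlap_penalty(1)))
  expect_identical(overlap_penalty(1), overlap_penalty(0.999))
})

test_that("joint loss enumerates the strict lower triangle", {
  sys1 <- harmonic_sys()
  wfs <- lapply(0:2, harmonic_eigenstate)
  batches <- lapply(1:3, function(i) {
    batch_from_ensemble(init_walkers(wfs[[i]], sys1, 400, seed = i, burn = 100))
  })
  jl <- joint_loss(wfs, sys1, batches, alpha = 1)
  expect_length(jl$penalty_terms, 3)   # pairs (1,0), (2,0), (2,1)
  expect_named(jl$penalty_terms, c("1>0", "2>0", "2>1"))
  jl0 <- joint_loss(wfs, sys1, batches, alpha = 0)
  expect_equal(jl0$total, sum(jl0$energy_terms), tolerance = 1e-14)
  jl1 <- joint_loss(wfs[1], sys1, batches[1], alpha = 1)
  expect_length(jl1$penalty_terms, 0)
  expect_equal(jl1$total, jl1$energy_terms[1], tolerance = 1e-14)
})

test_that("ground-state gradient is bit-identical to an unconstrained run", {
  sys1 <- harmonic_sys()
  wfs <- list(random_poly_gauss(1), random_poly_gauss(2))
  batches <- lapply(1:2, function(i) {
    batch_from_ensemble(init_walkers(wfs[[i]], sys1, 500, seed = i, burn = 100))
  })
  joint <- gradient_assembly(wfs, sys1, batches, alpha = 1)
  solo <- gradient_assembly(wfs[1], sys1, batches[1], alpha = 1)
  expect_identical(joint$grads[[1]], solo$grads[[1]])
  # alpha = 0 removes every penalty contribution exactly
  g0 <- gradient_assembly(wfs, sys1, batches, alpha = 0)
  ge <- grad_energy(wfs[[2]], sys1, batches[[2]])
  expect_equal(unname(as.numeric(g0$grads[[2]])),
               unname(as.numeric(excitedvmc:::clip_norm(as.numeric(ge), 10))),
               tolerance = 1e-14)
})

test_that("state n receives one penalty term per lower state", {
  sys1 <- harmonic_sys()
  wfs <- lapply(list(10, 11, 12), random_poly_gauss)
  batches <- lapply(1:3, function(i) {
    batch_from_ensemble(init_walkers(wfs[[i]], sys1, 500, seed = i, burn = 100))
  })
  ga <- gradient_assembly(wfs, sys1, batches, alpha = 1)
  expect_named(ga$overlaps, c("1>0", "2>0", "2>1"))
})

test_that("exponential smoothing obeys its closed forms", {
  expect_equal(ema_smooth(rep(3.7, 50), 0.99), rep(3.7, 50))
  x <- rnorm(20)
  expect_equal(ema_smooth(x, 1e-9), x, tolerance = 1e-6)
  # step response: after the step the bias-corrected EMA of a 0 -> 1 step
  # initialized at the step equals 1 - decay^m (scaled by the correction)
  k <- 10; m <- 15; decay <- 0.9
  x <- c(rep(0, k), rep(1, m))
  sm <- ema_smooth(x, decay)
  expected <- (1 - decay^m) / (1 - decay^(k + m))
  expect_equal(sm[k + m], expected, tolerance = 1e-12)
})

test_that("variance matching selects the brute-force closest checkpoint", {
  n_iter <- 500
  trace <- list(
    energy = matrix(0, n_iter, 2),
    variance = cbind(exp(seq(0, -4, length.out = n_iter)),
                     exp(seq(0.5, -2, length.out = n_iter))),
    checkpoint_iters = seq(100, 500, by = 100),
    decay = 0.99
  )
  class(trace) <- "training_trace"
  trace$variance_smooth <- apply(trace$variance, 2, ema_smooth, decay = 0.99)
  vm <- variance_match(trace, 1, 2)
  # state 2 ends with the higher variance: state 1 is rewound
  expect_equal(vm$rewound, 1)
  target <- trace$variance_smooth[n_iter, 2]
  dist <- abs(trace$variance_smooth[trace$checkpoint_iters, 1] - target)
  expect_equal(unname(vm$iter["1"]),
               trace$checkpoint_iters[max(which(dist == min(dist)))])
  expect_equal(unname(vm$iter["2"]), n_iter)
  expect_true(vm$matched)
  # equal final variances: both final checkpoints
  tr2 <- trace
  tr2$variance_smooth[n_iter, 1] <- tr2$variance_smooth[n_iter, 2]
  vm2 <- variance_match(tr2, 1, 2)
  expect_true(all(vm2$iter == n_iter))
  # target below the entire series: flagged unmatched
  tr3 <- trace
  tr3$variance_smooth[, 1] <- 10
  tr3$variance_smooth[n_iter, 2] <- 1e-9
  vm3 <- variance_match(tr3, 2, 1)
  expect_false(vm3$matched)
})

test_that("training is reproducible bit-exactly for identical seeds", {
  sys1 <- harmonic_sys()
  bl <- analytic_baseline(sys1, 2, perturb = 0.1, seed = 3)
  run <- function() {
    train_states(sys1, bl$states, n_iter = 15, batch_size = 200, lr = 0.05,
                 alpha = 1, seed = 21, burn = 50, decorr = 5,
                 checkpoint_every = 5, eval_samples = 400)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$trace$energy, f2$trace$energy)
  expect_identical(lapply(f1$states, wf_params), lapply(f2$states, wf_params))
  expect_identical(f1$result$energies[[1]]$value, f2$result$energies[[1]]$value)
  expect_identical(f1$result$pairs[["0-1"]]$overlap,
                   f2$result$pairs[["0-1"]]$overlap)
  # checkpoints restore bit-exactly
  wf_ck <- restore_checkpoint(f1, 1, 5)
  expect_identical(wf_params(wf_ck), f1$trace$checkpoints[["5"]][[1]])
})

test_that("the divergence guard aborts runaway training", {
  sys1 <- harmonic_sys()
  # an intentionally unstable configuration: huge learning rate
  bl <- analytic_baseline(sys1, 1, perturb = 0.3, seed = 9)
  expect_error(
    suppressWarnings(
      train_states(sys1, bl$states, n_iter = 400, batch_size = 100, lr = -0.2,
                   lr_decay = Inf, alpha = 0, seed = 2,
                   burn = 20, decorr = 2, optimizer = "sgd",
                   eval_samples = 100)
    ),
    class = "vmc_divergence"
  )
})
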