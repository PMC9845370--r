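# Configuration, geometry input, results output and the pipeline drivers
# behind the command-line tool (inst/scripts/excitedvmc).

.ELEMENTS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
               S = 16, Cl = 17, Ar = 18)

#' Read a molecular geometry from an XYZ file
#'
#' Standard XYZ: atom count, comment line, then `element x y z` per atom.
#' Units default to angstrom per the XYZ convention (conversion factor
#' 1 A = 1.8897259886 bohr); a `"bohr"` or `"angstrom"` tag in the comment
#' line, or the `units` argument, overrides. Electron counts follow from
#' `charge` and `multiplicity`: `N = sum(Z) - charge`,
#' `n_up - n_down = multiplicity - 1`.
#'
#' @param path XYZ file path.
#' @param units `NULL` (auto), `"bohr"` or `"angstrom"`.
#' @param charge total charge.
#' @param multiplicity spin multiplicity (2S + 1).
#' @return a `molecular_system`.
#' @export
load_geometry <- function(path, units = NULL, charge = 0L, multiplicity = 1L) {
  lines <- readLines(path)
  n_atoms <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n_atoms)) stop("malformed XYZ: first line must be the atom count")
  comment <- if (length(lines) >= 2) lines[2] else ""
  if (is.null(units)) {
    units <- if (grepl("bohr", comment, ignore.case = TRUE)) "bohr"
             else "angstrom"
  }
  units <- match.arg(units, c("bohr", "angstrom"))
  rows <- lines[3:(2 + n_atoms)]
  parts <- strsplit(trimws(rows), "\\s+")
  sym <- vapply(parts, `[[`, character(1), 1)
  unknown <- setdiff(sym, names(.ELEMENTS))
  if (length(unknown)) {
    stop(sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  Z <- .ELEMENTS[sym]
  pos <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (units == "angstrom") pos <- pos * BOHR_PER_ANGSTROM
  N <- sum(Z) - charge
  if (N < 1) stop("charge leaves no electrons")
  excess <- multiplicity - 1L
  if ((N - excess) %% 2L != 0L || excess > N || excess < 0) {
    stop(sprintf("charge %d / multiplicity %d inconsistent with %d electrons",
                 charge, multiplicity, N))
  }
  n_down <- (N - excess) %/% 2L
  molecular_system(unname(Z), pos, n_up = N - n_down, n_down = n_down)
}

# rolling polynomial hash over the serialized object; embedded in every
# output artifact so results can be traced to their configuration
.config_hash <- function(x) {
  bytes <- as.numeric(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read and validate a run configuration
#'
#' YAML with sections `system`, `ansatz`, `sampler`, `training`,
#' `evaluation`, `output`. Validation happens up front; a config hash is
#' embedded in every output artifact.
#'
#' @param path YAML file path (or a pre-parsed list).
#' @return validated config (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  required <- c("system", "training")
  for (blk in required) {
    if (is.null(cfg[[blk]])) stop(sprintf("config: missing '%s' block", blk))
  }
  sys_blk <- cfg$system
  if (is.null(sys_blk$model) && is.null(sys_blk$xyz)) {
    stop("config: system block needs 'model' (named model system) or 'xyz' (file path)")
  }
  defaults <- list(
    ansatz = list(degree = 5L, n_states = NULL),
    sampler = list(batch_size = 2000L, burn = 200L, decorr = 10L, seed = 1L),
    training = list(),
    evaluation = list(eval_samples = 20000L),
    output = list(dir = "vmc-results")
  )
  for (blk in names(defaults)) {
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]] %||% list())
  }
  tr <- cfg$training
  for (field in c("n_states", "n_iter")) {
    if (is.null(tr[[field]])) stop(sprintf("config: training block needs '%s'", field))
  }
  tr <- utils::modifyList(
    list(lr = 0.05, lr_decay = Inf, alpha = 1, checkpoint_every = 100L,
         ema_decay = 0.99, s_max = 0.999, perturb = 0.1),
    tr
  )
  cfg$training <- tr
  cfg$hash <- .config_hash(cfg[c("system", "ansatz", "sampler", "training")])
  class(cfg) <- "run_config"
  cfg
}

.config_system <- function(cfg) {
  sb <- cfg$system
  if (!is.null(sb$xyz)) {
    load_geometry(sb$xyz, units = sb$units,
                  charge = sb$charge %||% 0L,
                  multiplicity = sb$multiplicity %||% 1L)
  } else {
    model_system(sb$model,
                 d = sb$d %||% 1L,
                 n_particles = sb$n_particles %||% 1L,
                 omega = sb$omega %||% 1,
                 box_length = sb$box_length %||% 1,
                 soft = sb$soft %||% 1,
                 interaction = isTRUE(sb$interaction))
  }
}

#' Run a full train-and-evaluate pipeline from a config
#'
#' Builds the system, initializes the states from the analytic baseline (or
#' an imported baseline payload given as `system$baseline_json`), trains
#' with the overlap penalty, and writes the artifacts to the output
#' directory: `trace.csv` (per-iteration energies/variances/overlaps),
#' `spectrum.json`, and `checkpoints.rds`. Every artifact carries the
#' config hash and seed.
#'
#' @param config path to a YAML config or a parsed `run_config`.
#' @return the `vmc_fit`, invisibly.
#' @export
run_spectrum <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  system <- .config_system(cfg)
  tr <- cfg$training
  n <- tr$n_states
  if (!is.null(cfg$system$baseline_json)) {
    bl <- import_casscf(cfg$system$baseline_json, system, n)
  } else {
    bl <- analytic_baseline(system, n, degree = cfg$ansatz$degree,
                            perturb = tr$perturb, seed = cfg$sampler$seed)
  }
  fit <- train_states(
    system, bl$states, n_iter = tr$n_iter,
    batch_size = cfg$sampler$batch_size, lr = tr$lr, lr_decay = tr$lr_decay,
    alpha = tr$alpha, seed = cfg$sampler$seed, burn = cfg$sampler$burn,
    decorr = cfg$sampler$decorr, checkpoint_every = tr$checkpoint_every,
    ema_decay = tr$ema_decay, s_max = tr$s_max,
    eval_samples = cfg$evaluation$eval_samples
  )
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  write_fit(fit, cfg$output$dir, hash = cfg$hash)
  invisible(fit)
}

#' Write the artifacts of a fit
#'
#' @param fit a `vmc_fit`.
#' @param dir output directory.
#' @param hash config hash to embed.
#' @export
write_fit <- function(fit, dir, hash = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracedf <- as.data.frame(fit$trace$energy)
  names(tracedf) <- paste0("energy_", seq_len(ncol(tracedf)) - 1)
  vdf <- as.data.frame(fit$trace$variance)
  names(vdf) <- paste0("variance_", seq_len(ncol(vdf)) - 1)
  tracedf <- cbind(iteration = seq_len(nrow(tracedf)), tracedf, vdf)
  for (nm in names(fit$trace$overlaps)) {
    tracedf[[paste0("overlap_", gsub(">", "_", nm))]] <- fit$trace$overlaps[[nm]]
  }
  utils::write.csv(tracedf, file.path(dir, "trace.csv"), row.names = FALSE)
  jsonlite::write_json(
    spectrum_as_list(fit$result, hash = hash),
    file.path(dir, "spectrum.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  saveRDS(list(checkpoints = fit$trace$checkpoints,
               checkpoint_iters = fit$trace$checkpoint_iters,
               states = fit$states, seed = fit$seed, hash = hash),
          file.path(dir, "checkpoints.rds"))
  invisible(dir)
}

#' Spectrum result as a plain list (for JSON serialization)
#' @param result a `spectrum_result`.
#' @param hash config hash.
#' @export
spectrum_as_list <- function(result, hash = "") {
  list(
    config_hash = hash,
    seed = result$seed,
    eval_samples = result$eval_samples,
    states = lapply(seq_len(result$n_states), function(i) {
      e <- result$energies[[i]]
      list(state = i - 1L, energy = e$value, se = e$se, variance = e$variance)
    }),
    pairs = lapply(unname(result$pairs), function(p) {
      list(lower = p$lower, upper = p$upper,
           excitation_raw = p$excitation_raw,
           excitation_matched = p$excitation_matched,
           overlap = p$overlap, overlap_se = p$overlap_se,
           d2 = p$d2, oscillator_strength = p$oscillator_strength)
    })
  )
}

#' Estimator calibration against exact two-state mixtures
#'
#' Builds harmonic-trap mixture fixtures for each `eps`, samples both the
#' mixed state and the ground state, and reports the estimated overlap next
#' to the exact `sqrt(eps)`.
#'
#' @param eps_grid mixture weights.
#' @param batch_size walkers per state.
#' @param seed RNG seed.
#' @param burn burn-in steps.
#' @return data frame with `eps`, `exact`, `estimate`, `se`.
#' @export
mixture_calibrate <- function(eps_grid = c(0, 0.04, 0.25), batch_size = 10000L,
                              seed = 1L, burn = 500L) {
  sys1 <- model_system("harmonic")
  wf0 <- harmonic_eigenstate(0)
  wf1 <- harmonic_eigenstate(1)
  ens0 <- init_walkers(wf0, sys1, batch_size, seed = derive_seed(seed, 500L),
                       burn = burn)
  out <- lapply(seq_along(eps_grid), function(k) {
    eps <- eps_grid[k]
    fx <- make_mixture(eps, wf0, wf1)
    ensm <- init_walkers(fx$wf, sys1, batch_size,
                         seed = derive_seed(seed, 600L + k), burn = burn)
    S <- overlap_estimate(fx$wf, wf0, ensm, ens0)
    data.frame(eps = eps, exact = fx$overlap0, estimate = S$value, se = S$se)
  })
  do.call(rbind, out)
}

#' Grid-oracle reference for a configured system
#'
#' @param config path to a YAML config or parsed `run_config`.
#' @param out optional JSON output path.
#' @return the `grid_solution`, invisibly.
#' @export
run_oracle <- function(config, out = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  system <- .config_system(cfg)
  sol <- grid_eigensolve(system, cfg$training$n_states)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(config_hash = cfg$hash, energies = sol$energies,
           spacing = sol$spacing, kind = sol$kind),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(sol)
}
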