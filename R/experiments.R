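#' Experiment configuration
#'
#' Bundles everything a run needs: mesh resolution, kinetics,
#' deformation, horizon, initial-condition noise and seeding, ensemble
#' size and the (F, k) phase-diagram grids. A configuration plus a seed
#' fully determines a run. Round-trips losslessly through YAML.
#'
#' @param subdivisions icosphere subdivision level.
#' @param radius initial sphere radius.
#' @param F,k,Du,Dv,dt see [gray_scott_params()].
#' @param alpha,driver,refinement_threshold,snapshot_every see
#'   [deformation_params()].
#' @param horizon iterations per run.
#' @param band_half_width angular half-width (radians) of the seeded
#'   great-circle band.
#' @param band_u,band_v morphogen values inside the band.
#' @param noise_amplitude white-noise amplitude added to `u`, `v` inside
#'   the band.
#' @param seed base random seed.
#' @param ensemble_size realizations for the ensemble study.
#' @param F_grid,k_grid parameter grids for the phase diagram (defaults:
#'   4 x 7 = 28 couples spanning F 0.02-0.05 by 0.01 and k 0.035-0.065
#'   by 0.005, containing the normal / polymicrogyria / lissencephaly
#'   reference pairs).
#' @param smoothing_iterations smoothing sweeps before inter-mesh
#'   interpolation.
#' @param lumped_mass use lumped mass matrices.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(subdivisions = 3L, radius = 1,
                              F = 0.04, k = 0.06, Du = 2e-3, Dv = 1e-3,
                              dt = 1, alpha = 0.00025, driver = "u",
                              refinement_threshold = 2,
                              snapshot_every = 100L, horizon = 1500L,
                              band_half_width = 0.15, band_u = 0.5,
                              band_v = 0.25, noise_amplitude = 0.1,
                              seed = 1L, ensemble_size = 10L,
                              F_grid = seq(0.02, 0.05, by = 0.01),
                              k_grid = seq(0.035, 0.065, by = 0.005),
                              smoothing_iterations = 100L,
                              lumped_mass = FALSE) {
  cfg <- list(subdivisions = as.integer(subdivisions), radius = radius,
              F = F, k = k, Du = Du, Dv = Dv, dt = dt, alpha = alpha,
              driver = driver, refinement_threshold = refinement_threshold,
              snapshot_every = as.integer(snapshot_every),
              horizon = as.integer(horizon),
              band_half_width = band_half_width, band_u = band_u,
              band_v = band_v, noise_amplitude = noise_amplitude,
              seed = as.integer(seed),
              ensemble_size = as.integer(ensemble_size),
              F_grid = F_grid, k_grid = k_grid,
              smoothing_iterations = as.integer(smoothing_iterations),
              lumped_mass = isTRUE(lumped_mass))
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' @rdname experiment_config
#' @param cfg an `experiment_config`.
#' @export
config_gray_scott <- function(cfg)
  gray_scott_params(F = cfg$F, k = cfg$k, Du = cfg$Du, Dv = cfg$Dv,
                    dt = cfg$dt)

#' @rdname experiment_config
#' @export
config_deformation <- function(cfg)
  deformation_params(alpha = cfg$alpha, driver = cfg$driver,
                     refinement_threshold = cfg$refinement_threshold,
                     snapshot_every = cfg$snapshot_every)

#' Seeded-line initial condition
#'
#' The homogeneous equilibrium `(u, v) = (1, 0)` perturbed along a broad
#' great-circle band: vertices within `band_half_width` radians of the
#' equator get `(band_u, band_v)` plus independent uniform white noise
#' of the given amplitude on both species. The band is the model's
#' sulcal-root analogue: the seed around which the main fold organizes.
#'
#' @param mesh the initial sphere mesh.
#' @param noise_amplitude uniform noise half-range inside the band.
#' @param seed integer seed; the state is reproducible given the seed.
#' @param band_half_width angular half-width in radians (default 0.15).
#' @param band_u,band_v in-band morphogen values (defaults 0.5, 0.25).
#' @return a `morphogen_state`.
#' @export
initial_condition_line <- function(mesh, noise_amplitude = 0.1,
                                   seed = 1L, band_half_width = 0.15,
                                   band_u = 0.5, band_v = 0.25) {
  n <- nrow(mesh$vertices)
  r <- sqrt(rowSums(mesh$vertices^2))
  lat <- asin(pmax(-1, pmin(1, mesh$vertices[, 3] / r)))
  band <- abs(lat) <= band_half_width
  u <- rep(1, n); v <- rep(0, n)
  u[band] <- band_u
  v[band] <- band_v
  if (noise_amplitude > 0) {
    set.seed(as.integer(seed))
    nb <- sum(band)
    u[band] <- u[band] + stats::runif(nb, -noise_amplitude, noise_amplitude)
    v[band] <- v[band] + stats::runif(nb, -noise_amplitude, noise_amplitude)
  }
  # concentrations are non-negative
  morphogen_state(pmax(u, 0), pmax(v, 0))
}

#' Run one configured simulation
#'
#' Builds the icosphere, draws the seeded-line initial condition and
#' runs the coupled loop.
#'
#' @param cfg an `experiment_config`.
#' @param seed seed override (default `cfg$seed`).
#' @param ... passed to [run_simulation()].
#' @return a `cortical_sim`.
#' @export
run_configured <- function(cfg, seed = cfg$seed, ...) {
  mesh <- make_icosphere(cfg$subdivisions, cfg$radius)
  state <- initial_condition_line(mesh, cfg$noise_amplitude, seed,
                                  cfg$band_half_width, cfg$band_u,
                                  cfg$band_v)
  run_simulation(mesh, state, config_gray_scott(cfg),
                 config_deformation(cfg), horizon = cfg$horizon,
                 lumped_mass = cfg$lumped_mass, ...)
}

#' Ensemble of noisy realizations
#'
#' Runs `ensemble_size` simulations from independent noisy seeded-line
#' initial conditions (seeds `seed + 0 ... seed + n - 1`), transfers the
#' final binary fold maps onto the undeformed reference sphere,
#' re-binarizes at 0.5 and aggregates them into the reproducibility map
#' `S` (percent). Also averages the radial displacement fields into an
#' average surface and counts the segments of the main fold per
#' realization. A failed realization is recorded, warned about and
#' excluded; the ensemble proceeds while at least 2 succeed.
#'
#' @param cfg an `experiment_config` with `ensemble_size >= 2`.
#' @param verbose print one line per realization.
#' @return list of class `fold_ensemble`: `bmaps` (per realization, on
#'   the reference), `S`, `average_surface` (`triangle_mesh`),
#'   `fold_counts`, `main_fold_segments`, `failed`, `reference_mesh`.
#' @export
run_ensemble <- function(cfg, verbose = FALSE) {
  stopifnot(cfg$ensemble_size >= 2)
  reference <- make_icosphere(cfg$subdivisions, cfg$radius)
  ref_dir <- reference$vertices / cfg$radius
  bmaps <- list(); radials <- list()
  fold_counts <- integer(0); segs <- integer(0); failed <- integer(0)
  for (i in seq_len(cfg$ensemble_size) - 1L) {
    res <- tryCatch({
      sim <- run_configured(cfg, seed = cfg$seed + i,
                            record_curvature = FALSE)
      s <- sim$snapshots[[length(sim$snapshots)]]
      b <- threshold_map(mean_curvature(s$mesh))
      br <- as.integer(resample_field(s$mesh, as.numeric(b), reference,
                                      cfg$smoothing_iterations) > 0.5)
      ctr <- colMeans(s$mesh$vertices)
      rad <- sqrt(rowSums(sweep(s$mesh$vertices, 2, ctr)^2))
      rr <- resample_field(s$mesh, rad, reference,
                           cfg$smoothing_iterations)
      list(b = br, r = rr,
           n = segment_folds(b, s$mesh)$n_folds,
           m = main_fold_segments(br, reference, cfg$band_half_width))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("realization %d failed: %s", i + 1L,
                      conditionMessage(res)), call. = FALSE)
      failed <- c(failed, i + 1L)
      next
    }
    bmaps[[length(bmaps) + 1L]] <- res$b
    radials[[length(radials) + 1L]] <- res$r
    fold_counts <- c(fold_counts, res$n)
    segs <- c(segs, res$m)
    if (verbose)
      message(sprintf("  realization %d/%d: %d folds, main fold in %d part(s)",
                      i + 1L, cfg$ensemble_size, res$n, res$m))
  }
  if (length(bmaps) < 2) stop("fewer than 2 realizations succeeded")
  mean_rad <- Reduce(`+`, radials) / length(radials)
  avg_surface <- triangle_mesh(ref_dir * mean_rad, reference$faces,
                               validate = FALSE)
  structure(list(bmaps = bmaps, S = ensemble_map(bmaps),
                 average_surface = avg_surface, fold_counts = fold_counts,
                 main_fold_segments = segs, failed = failed,
                 reference_mesh = reference, config = cfg),
            class = "fold_ensemble")
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat(sprintf("fold_ensemble: %d realizations (%d failed)\n",
              length(x$bmaps), length(x$failed)))
  cat(sprintf("  S map: max %.1f%%, mean %.1f%%\n", max(x$S), mean(x$S)))
  cat(sprintf("  final fold counts: %s\n",
              paste(x$fold_counts, collapse = " ")))
  cat(sprintf("  main fold segments: %s\n",
              paste(x$main_fold_segments, collapse = " ")))
  invisible(x)
}

#' (F, k) phase diagram
#'
#' Runs one simulation per (F, k) couple of the configured grids (fixed
#' seed) and classifies the final pattern regime. A failed cell is
#' labeled `"failed"` and the sweep continues.
#'
#' @param cfg an `experiment_config`; its `F_grid` x `k_grid` (default
#'   4 x 7 = 28 couples) defines the sweep.
#' @param verbose print one line per cell.
#' @return data.frame with columns `F`, `k`, `regime`,
#'   `pathology_analogue`, `n_folds`, `v_variance`, `mean_elongation`.
#' @export
phase_diagram <- function(cfg, verbose = FALSE) {
  grid <- expand.grid(F = cfg$F_grid, k = cfg$k_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty (F, k) grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$F <- grid$F[i]; cfg_i$k <- grid$k[i]
    out <- tryCatch({
      sim <- run_configured(cfg_i, record_curvature = FALSE)
      classify_regime(sim)
    }, error = function(e) list(regime = "failed",
                                pathology_analogue = NA_character_,
                                n_folds = NA_integer_,
                                v_variance = NA_real_,
                                mean_elongation = NA_real_))
    if (verbose)
      message(sprintf("  F=%.3f k=%.3f -> %s", grid$F[i], grid$k[i],
                      out$regime))
    data.frame(F = grid$F[i], k = grid$k[i], regime = out$regime,
               pathology_analogue = out$pathology_analogue,
               n_folds = out$n_folds, v_variance = out$v_variance,
               mean_elongation = out$mean_elongation)
  })
  do.call(rbind, rows)
}
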