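#' Deformation parameters
#'
#' Growth of the surface is a displacement of every vertex along its
#' outward unit normal, at a rate `alpha` times a linear function of one
#' morphogen. The substrate `u` is the default driver: the substrate-rich
#' background expands while activator-rich regions lag behind and sink
#' into concave folds, so the seeded activator line becomes the
#' reproducible main sulcus (the sulcal-root picture). Driving with the
#' autocatalyst `v` instead makes activator regions bulge outward as
#' gyri, with folds forming in their complement.
#'
#' @param alpha deformation gain (length per unit morphogen per unit
#'   time). Keep the per-step displacement well below the mean edge
#'   length; a warning is issued above 10 percent.
#' @param driver `"u"` (default) or `"v"`.
#' @param refinement_threshold area ratio triggering triangle refinement
#'   (default 2).
#' @param snapshot_every record a snapshot every this many iterations.
#' @export
deformation_params <- function(alpha = 0.00025, driver = "u",
                               refinement_threshold = 2,
                               snapshot_every = 100L) {
  driver <- match.arg(driver, c("u", "v"))
  stopifnot(alpha >= 0, refinement_threshold > 0, snapshot_every >= 1)
  structure(list(alpha = alpha, driver = driver,
                 refinement_threshold = refinement_threshold,
                 snapshot_every = as.integer(snapshot_every)),
            class = "deformation_params")
}

#' Morphogen-to-growth map
#'
#' The simplest growth law: the selected morphogen itself (identity
#' linear function). `scale` and `offset` allow any affine variant
#' `scale * field + offset`; the defaults reduce to the identity.
#'
#' @param u,v per-vertex morphogen fields.
#' @param params a `deformation_params`.
#' @param scale,offset affine coefficients.
#' @return per-vertex growth rate field.
#' @export
growth_function <- function(u, v, params, scale = 1, offset = 0) {
  field <- switch(params$driver, v = v, u = u,
                  stop("unknown deformation driver: ", params$driver))
  scale * field + offset
}

#' Displace vertices along their outward normals
#'
#' `x_i <- x_i + dt * alpha * f_i * n_i` with `n_i` the outward unit
#' vertex normal. Connectivity is unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param f per-vertex growth field.
#' @param alpha deformation gain.
#' @param dt time step.
#' @param geometry `mesh_geometry` of `mesh` (for the vertex normals).
#' @export
deform_vertices <- function(mesh, f, alpha, dt,
                            geometry = mesh_geometry(mesh)) {
  if (!all(is.finite(f))) stop("non-finite growth field")
  v <- mesh$vertices + (dt * alpha * f) * geometry$vertex_normal
  if (!all(is.finite(v))) stop("non-finite vertex positions")
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

#' Run the coupled reaction-diffusion / surface-growth simulation
#'
#' Per iteration: assemble the P1 operators on the current mesh, take one
#' IMEX chemistry step (the dilution rate from the previous deformation
#' enters the implicit diagonal), displace vertices along their normals
#' by `alpha * f`, measure the new metric to obtain the next dilution
#' field, then refine any triangle whose area exceeds the threshold
#' (interpolating `u`, `v` and the dilution to the inserted midpoints).
#' With `alpha = 0` the loop reduces bit-for-bit to the static-surface
#' dynamics.
#'
#' @param mesh initial `triangle_mesh` (normally an icosphere).
#' @param state initial `morphogen_state` on that mesh.
#' @param gs `gray_scott_params`.
#' @param dp `deformation_params`.
#' @param horizon number of iterations (>= 1).
#' @param lumped_mass use the lumped mass matrix.
#' @param record_curvature compute the mean-curvature map at snapshots.
#' @param verbose print progress every 500 iterations.
#' @return a `cortical_sim` object: list with `snapshots` (each holding
#'   `time`, `mesh`, `u`, `v`, `curvature`), the per-iteration `area`
#'   series, `times`, the final `mesh`/`state`, and the parameter set.
#' @export
run_simulation <- function(mesh, state, gs = gray_scott_params(),
                           dp = deformation_params(), horizon = 1500L,
                           lumped_mass = FALSE, record_curvature = TRUE,
                           verbose = FALSE) {
  stopifnot(horizon >= 1)
  geom <- mesh_geometry(mesh)
  reference_area <- geom$total_area / nrow(mesh$faces)
  mean_edge <- sqrt(4 * reference_area / sqrt(3))   # equilateral estimate
  area_series <- numeric(horizon + 1L)
  area_series[1L] <- geom$total_area
  snaps <- list()
  take_snapshot <- function(mesh, geom, state, fem = NULL) {
    curv <- if (record_curvature)
      mean_curvature(mesh, geom, fem) else NULL
    list(time = state$time, mesh = mesh, u = state$u, v = state$v,
         curvature = curv)
  }
  snaps[[1L]] <- take_snapshot(mesh, geom, state)
  fem <- NULL
  bounds_warned <- FALSE
  for (it in seq_len(horizon)) {
    tmpl <- if (!is.null(fem) && fem$vertex_count == nrow(mesh$vertices))
      fem$chol_template else NULL
    fem <- fem_system(mesh, geom, lumped = lumped_mass,
                      chol_template = tmpl)
    state <- step_fields(state, gs, fem)
    if (dp$alpha > 0) {
      f <- growth_function(state$u, state$v, dp)
      disp <- gs$dt * dp$alpha * max(abs(f))
      if (disp > 0.1 * mean_edge)
        warning(sprintf(paste0("iteration %d: per-step displacement ",
                               "%.2g exceeds 10%% of mean edge %.2g"),
                        it, disp, mean_edge), call. = FALSE)
      mesh2 <- deform_vertices(mesh, f, dp$alpha, gs$dt, geom)
      geom2 <- mesh_geometry(mesh2)
      dil <- dilution_field(geom, geom2, gs$dt, mesh2$faces)
      ref <- refine_mesh(mesh2, fields = list(u = state$u, v = state$v,
                                              dilution = dil),
                         reference_area = reference_area,
                         threshold_factor = dp$refinement_threshold)
      mesh <- ref$mesh
      geom <- if (nrow(mesh$vertices) == nrow(mesh2$vertices)) geom2
              else mesh_geometry(mesh)
      state <- morphogen_state(ref$fields$u, ref$fields$v,
                               time = state$time,
                               dilution = ref$fields$dilution)
    }
    if (!bounds_warned &&
        (min(state$u, state$v) < -1e-6 || max(state$u, state$v) > 1 + 1e-6)) {
      warning(sprintf("iteration %d: concentrations left [0, 1] + 1e-6", it),
              call. = FALSE)
      bounds_warned <- TRUE
    }
    area_series[it + 1L] <- geom$total_area
    if (it %% dp$snapshot_every == 0L || it == horizon)
      snaps[[length(snaps) + 1L]] <- take_snapshot(mesh, geom, state)
    if (verbose && it %% 500L == 0L)
      message(sprintf("  iter %d/%d: %d vertices, area %.3f", it, horizon,
                      nrow(mesh$vertices), geom$total_area))
  }
  structure(list(snapshots = snaps,
                 times = vapply(snaps, `[[`, numeric(1), "time"),
                 area = area_series,
                 mesh = mesh, state = state,
                 params = list(gray_scott = gs, deformation = dp,
                               horizon = as.integer(horizon),
                               lumped_mass = lumped_mass)),
            class = "cortical_sim")
}

#' @export
print.cortical_sim <- function(x, ...) {
  gs <- x$params$gray_scott
  cat("cortical_sim: Gray-Scott folding simulation\n")
  cat(sprintf("  F = %g, k = %g, Du = %g, Dv = %g, dt = %g\n",
              gs$F, gs$k, gs$Du, gs$Dv, gs$dt))
  cat(sprintf("  alpha = %g (driver %s), horizon %d, %d snapshots\n",
              x$params$deformation$alpha, x$params$deformation$driver,
              x$params$horizon, length(x$snapshots)))
  cat(sprintf("  mesh: %d -> %d vertices; area %.4f -> %.4f\n",
              nrow(x$snapshots[[1]]$mesh$vertices), nrow(x$mesh$vertices),
              x$area[1], x$area[length(x$area)]))
  invisible(x)
}

#' @export
summary.cortical_sim <- function(object, ...) {
  fc <- fold_count_series(object)
  reg <- classify_regime(object)
  out <- list(final_time = object$state$time,
              vertices = nrow(object$mesh$vertices),
              area_initial = object$area[1],
              area_final = object$area[length(object$area)],
              v_variance = stats::var(object$state$v),
              fold_counts = fc,
              regime = reg)
  class(out) <- "summary.cortical_sim"
  out
}

#' @export
print.summary.cortical_sim <- function(x, ...) {
  cat(sprintf("final time %g, %d vertices\n", x$final_time, x$vertices))
  cat(sprintf("area %.4f -> %.4f (ratio %.3f)\n", x$area_initial,
              x$area_final, x$area_final / x$area_initial))
  cat(sprintf("spatial variance of v: %.3e\n", x$v_variance))
  cat(sprintf("final fold count: %d\n",
              x$fold_counts$count[nrow(x$fold_counts)]))
  cat(sprintf("regime: %s (mean elongation %.2f)\n", x$regime$regime,
              x$regime$mean_elongation))
  invisible(x)
}

#' @export
plot.cortical_sim <- function(x, which = c("area", "folds"), ...) {
  which <- match.arg(which)
  if (which == "area") {
    graphics::plot(seq_along(x$area) - 1L, x$area, type = "l",
                   xlab = "iteration", ylab = "surface area",
                   main = "Surface area growth", ...)
  } else {
    fc <- fold_count_series(x)
    graphics::plot(fc$time, fc$count, type = "s", xlab = "time",
                   ylab = "number of folds",
                   main = "Fold count along time", ...)
  }
  invisible(x)
}
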