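#' Gray-Scott kinetic parameters
#'
#' The two-species Gray-Scott system: a substrate `u` is fed at rate `F`
#' and consumed by cubic autocatalysis `u v^2`; the autocatalyst `v` is
#' produced by the same term and removed at rate `F + k`. `Du` and `Dv`
#' are the diffusion coefficients (classically `Du = 2 Dv`, the
#' long-range substrate / short-range autocatalyst split behind the
#' Turing instability), and `dt` the time step of the semi-implicit
#' integrator.
#'
#' @param F feed rate (1/time).
#' @param k kill rate (1/time).
#' @param Du,Dv diffusion coefficients (length^2/time).
#' @param dt time step.
#' @return an object of class `gray_scott_params`.
#' @export
gray_scott_params <- function(F = 0.04, k = 0.06, Du = 2e-3, Dv = 1e-3,
                              dt = 1) {
  stopifnot(F > 0, k > 0, Du > 0, Dv > 0, dt > 0)
  if (F > 0.1 || k > 0.1)
    warning("F, k outside the (0, 0.1] range of the studied regimes")
  structure(list(F = F, k = k, Du = Du, Dv = Dv, dt = dt),
            class = "gray_scott_params")
}

#' Gray-Scott reaction terms
#'
#' @param u,v concentrations (scalars or vectors).
#' @param params a `gray_scott_params`.
#' @return list with `du` = `-u v^2 + F (1 - u)` and
#'   `dv` = `u v^2 - (F + k) v`.
#' @export
reaction_terms <- function(u, v, params) {
  uvv <- u * v^2
  list(du = -uvv + params$F * (1 - u),
       dv = uvv - (params$F + params$k) * v)
}

#' Homogeneous steady states of the Gray-Scott kinetics
#'
#' `(1, 0)` is always a fixed point. When the discriminant
#' `F - 4 (F + k)^2` is non-negative two further roots exist, with
#' `v = F (1 +/- sqrt(1 - 4 (F+k)^2 / F)) / (2 (F + k))` and
#' `u = (F + k) / v`.
#'
#' @param params a `gray_scott_params`.
#' @return list of `c(u, v)` pairs, the trivial state first.
#' @export
homogeneous_equilibria <- function(params) {
  F <- params$F; A <- params$F + params$k
  eq <- list(c(u = 1, v = 0))
  disc <- F - 4 * A^2
  # treat a discriminant at rounding distance of zero as the degenerate
  # saddle-node case (e.g. F = 0.04, k = 0.06 is exactly on the curve)
  if (disc >= -1e-12 * F) {
    disc <- max(disc, 0)
    rt <- sqrt(disc * F)                  # = F * sqrt(1 - 4A^2/F)
    for (vv in c((F + rt) / (2 * A), (F - rt) / (2 * A))) {
      eq[[length(eq) + 1L]] <- c(u = A / vv, v = vv)
      if (disc == 0) break                 # degenerate double root
    }
  }
  eq
}

#' Morphogen state on a mesh
#'
#' Bundles the per-vertex fields `u`, `v`, the simulation time and the
#' per-vertex dilution rate carried over from the previous deformation
#' (zero on the first step by convention).
#'
#' @param u,v per-vertex concentrations.
#' @param time simulation time.
#' @param dilution per-vertex metric dilution rate (1/time).
#' @export
morphogen_state <- function(u, v, time = 0, dilution = numeric(length(u))) {
  stopifnot(length(u) == length(v), length(dilution) == length(u))
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("non-finite morphogen fields")
  structure(list(u = as.numeric(u), v = as.numeric(v), time = time,
                 dilution = as.numeric(dilution)),
            class = "morphogen_state")
}

#' Metric dilution rate of a growing surface
#'
#' On a growing domain, local area expansion thins concentrations at the
#' rate `(1/sqrt(g)) d sqrt(g) / dt`, with `sqrt(g)` the square root of
#' the metric determinant (twice the triangle area). The rate is
#' estimated per face by a backward difference
#' `(sqrt_g(t) - sqrt_g(t - dt)) / (dt * sqrt_g(t))` and averaged onto
#' vertices with incident-face-area weights. Geometry at the next step
#' is unknowable in this Lagrangian setting, which is why the backward
#' difference is used.
#'
#' @param geom_prev,geom_curr `mesh_geometry` of the same connectivity
#'   before and after a deformation step.
#' @param dt elapsed time.
#' @param faces the shared face matrix.
#' @return per-vertex dilution rate (1/time).
#' @export
dilution_field <- function(geom_prev, geom_curr, dt, faces) {
  if (length(geom_prev$sqrt_g) != length(geom_curr$sqrt_g))
    stop("dilution_field: meshes have different connectivity")
  d_face <- (geom_curr$sqrt_g - geom_prev$sqrt_g) /
    (dt * geom_curr$sqrt_g)
  n <- max(faces)
  a <- geom_curr$face_area
  num <- tapply_sum(a * d_face, faces[, 1], n) +
    tapply_sum(a * d_face, faces[, 2], n) +
    tapply_sum(a * d_face, faces[, 3], n)
  den <- tapply_sum(a, faces[, 1], n) + tapply_sum(a, faces[, 2], n) +
    tapply_sum(a, faces[, 3], n)
  num / den
}

#' One semi-implicit (IMEX) reaction-diffusion step
#'
#' Advances `u`, `v` by `dt` on the current mesh. Diffusion, the linear
#' removal terms, the dilution term and the lagged nonlinear coefficient
#' `(v^n)^2` are implicit; the remaining sources (`F` feed, `u v^2`
#' production) are explicit:
#' \deqn{(M + dt\,D_u K + dt\,\tilde M[(v^n)^2 + F + d])\,u^{n+1} =
#'       M u^n + dt\,F\,M 1}
#' \deqn{(M + dt\,D_v K + dt\,\tilde M[F + k + d])\,v^{n+1} =
#'       M v^n + dt\,M (u^n (v^n)^2)}
#' where \eqn{\tilde M[w]} is the lumped mass scaled per vertex by `w`.
#' Both system matrices are symmetric positive definite for all
#' admissible states, so each step is two sparse SPD solves.
#'
#' @param state a `morphogen_state` (its `dilution` field enters the
#'   implicit diagonal).
#' @param params a `gray_scott_params`.
#' @param fem a `fem_system` assembled on the state's mesh.
#' @param tol solver tolerance passed to [solve_spd()].
#' @return the advanced `morphogen_state` (same mesh, `time + dt`).
#' @export
step_fields <- function(state, params, fem, tol = 1e-10) {
  u <- state$u; v <- state$v; dil <- state$dilution
  n <- fem$vertex_count
  stopifnot(length(u) == n)
  dt <- params$dt
  M <- fem$mass; K <- fem$stiffness; ml <- fem$mass_lumped
  du_diag <- ml * (v^2 + params$F + dil)
  dv_diag <- ml * (params$F + params$k + dil)
  if (any(du_diag < 0) || any(dv_diag < 0))
    stop("pathological shrinkage: negative implicit diagonal")
  if (!is.null(fem$stiff_x) && !isTRUE(fem$lumped)) {
    # single-pass assembly of M + dt D K + dt diag from stored triplets
    ii <- c(fem$trip_i, seq_len(n)); jj <- c(fem$trip_j, seq_len(n))
    Au <- Matrix::sparseMatrix(
      i = ii, j = jj, x = c(fem$mass_x + (dt * params$Du) * fem$stiff_x,
                            dt * du_diag),
      dims = c(n, n), symmetric = TRUE)
    Av <- Matrix::sparseMatrix(
      i = ii, j = jj, x = c(fem$mass_x + (dt * params$Dv) * fem$stiff_x,
                            dt * dv_diag),
      dims = c(n, n), symmetric = TRUE)
  } else {
    Au <- M + (dt * params$Du) * K + Matrix::Diagonal(n, dt * du_diag)
    Av <- M + (dt * params$Dv) * K + Matrix::Diagonal(n, dt * dv_diag)
  }
  Mu <- as.numeric(M %*% u)
  bu <- Mu + dt * params$F * Matrix::rowSums(M)
  bv <- as.numeric(M %*% v) + dt * as.numeric(M %*% (u * v^2))
  u1 <- step_solve(Au, bu, fem, tol)
  v1 <- step_solve(Av, bv, fem, tol)
  if (!all(is.finite(u1)) || !all(is.finite(v1)))
    stop("non-finite fields after step")
  morphogen_state(u1, v1, time = state$time + dt, dilution = dil)
}

# SPD solve reusing the fem system's symbolic Cholesky analysis; falls
# back to the general solver. Same residual contract as solve_spd.
step_solve <- function(A, b, fem, tol) {
  if (is.null(fem$chol_template)) return(solve_spd(A, b, tol))
  ch <- tryCatch(Matrix::update(fem$chol_template, A),
                 error = function(e) NULL)
  if (is.null(ch)) return(solve_spd(A, b, tol))
  x <- as.numeric(Matrix::solve(ch, b, system = "A"))
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(x)
  res <- sqrt(sum(as.numeric(A %*% x - b)^2)) / nb
  if (!is.finite(res) || res > tol)
    stop(sprintf("step_solve: residual %.3e exceeds tol %.3e", res, tol))
  x
}
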