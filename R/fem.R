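#' P1 finite elements on a triangle mesh
#'
#' Assembles the mass matrix `M` (`M_ij = integral phi_i phi_j`) and the
#' stiffness matrix `K` (`K_ij = integral grad phi_i . grad phi_j` in the
#' surface metric, i.e. the Laplace-Beltrami operator in weak form) for
#' continuous piecewise-affine hat functions on the mesh. On each
#' triangle the mass contribution is `area/6` on the diagonal and
#' `area/12` off it; the stiffness diagonal is `area / h_i^2` with `h_i`
#' the triangle height from vertex `i` (the hat gradient has magnitude
#' `1/h_i`), and the off-diagonal entries are the corresponding gradient
#' dot products — the classic cotangent weights.
#'
#' @param mesh a `triangle_mesh`.
#' @param geometry its `mesh_geometry` (computed if missing).
#' @param lumped if TRUE the mass matrix is the row-sum (barycentric)
#'   diagonal lumping; the consistent form is the default.
#' @param chol_template optional symbolic Cholesky analysis from a
#'   previous `fem_system` on a mesh with identical connectivity
#'   (reused instead of re-analyzed; the coupled loop passes it along).
#' @return a list of class `fem_system` with sparse symmetric `mass`,
#'   `stiffness`, the lumped diagonal `mass_lumped` and `vertex_count`.
#' @export
fem_system <- function(mesh, geometry = mesh_geometry(mesh),
                       lumped = FALSE, chol_template = NULL) {
  f <- mesh$faces; n <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 1], f[, 2])
  j <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 3])
  ti <- pmin(i, j); tj <- pmax(i, j)
  mx <- mass_triplets(geometry)
  kx <- stiffness_triplets(mesh, geometry)
  M <- if (lumped) Matrix::Diagonal(n, x = geometry$vertex_area)
       else Matrix::sparseMatrix(i = ti, j = tj, x = mx, dims = c(n, n),
                                 symmetric = TRUE)
  K <- Matrix::sparseMatrix(i = ti, j = tj, x = kx, dims = c(n, n),
                            symmetric = TRUE)
  # symbolic Cholesky analysis of the step-matrix pattern (M + K + diag),
  # reused by every implicit solve on this mesh
  if (is.null(chol_template))
    chol_template <- tryCatch(
      Matrix::Cholesky(K + Matrix::Diagonal(n), LDL = FALSE),
      error = function(e) NULL)
  structure(list(mass = M, stiffness = K,
                 mass_lumped = geometry$vertex_area,
                 vertex_count = n,
                 trip_i = ti, trip_j = tj,
                 mass_x = if (lumped) NULL else mx, stiff_x = kx,
                 lumped = lumped, chol_template = chol_template),
            class = "fem_system")
}

# upper-triangle triplet values (same (i,j) layout as fem_system builds):
# diagonal entries first (area/6 per incident face), then the three
# off-diagonal pairs (area/12)
mass_triplets <- function(geometry) {
  a <- geometry$face_area
  c(a / 6, a / 6, a / 6, a / 12, a / 12, a / 12)
}

stiffness_triplets <- function(mesh, geometry) {
  v <- mesh$vertices; f <- mesh$faces
  a <- geometry$face_area
  o1 <- v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE]
  o2 <- v[f[, 1], , drop = FALSE] - v[f[, 3], , drop = FALSE]
  o3 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  c(rowSums(o1 * o1), rowSums(o2 * o2), rowSums(o3 * o3),
    rowSums(o1 * o2), rowSums(o1 * o3), rowSums(o2 * o3)) / rep(4 * a, 6)
}

#' @rdname fem_system
#' @export
assemble_mass <- function(mesh, geometry = mesh_geometry(mesh),
                          lumped = FALSE) {
  f <- mesh$faces; n <- nrow(mesh$vertices)
  if (lumped)
    return(Matrix::Diagonal(n, x = geometry$vertex_area))
  i <- c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 1], f[, 2])
  j <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 3])
  Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j),
                       x = mass_triplets(geometry), dims = c(n, n),
                       symmetric = TRUE)
}

#' @rdname fem_system
#' @export
assemble_stiffness <- function(mesh, geometry = mesh_geometry(mesh)) {
  f <- mesh$faces; n <- nrow(mesh$vertices)
  # edge opposite vertex k, cyclic: o1 = x3-x2, o2 = x1-x3, o3 = x2-x1;
  # grad phi_k = rot90(o_k)/(2A) so grad_i . grad_j = (o_i . o_j)/(4A^2)
  i <- c(f[, 1], f[, 2], f[, 3], f[, 1], f[, 1], f[, 2])
  j <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 3])
  Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j),
                       x = stiffness_triplets(mesh, geometry),
                       dims = c(n, n), symmetric = TRUE)
}

#' Solve a sparse symmetric positive-definite system
#'
#' Direct sparse Cholesky factorization with a verified residual
#' contract: the returned `x` satisfies `||Ax - b|| / ||b|| <= tol`,
#' otherwise an error carrying the achieved residual is raised.
#'
#' @param A sparse symmetric positive-definite matrix.
#' @param b right-hand side vector.
#' @param tol relative residual bound (default 1e-10).
#' @export
solve_spd <- function(A, b, tol = 1e-10) {
  A <- Matrix::forceSymmetric(A)
  x <- as.numeric(Matrix::solve(A, b))
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(x)
  res <- sqrt(sum(as.numeric(A %*% x - b)^2)) / nb
  if (!is.finite(res) || res > tol)
    stop(sprintf("solve_spd: residual %.3e exceeds tol %.3e", res, tol))
  x
}

#' Write a sparse operator in Matrix Market coordinate format
#' @param A sparse matrix.
#' @param path output file (.mtx).
#' @export
write_mtx <- function(A, path) {
  Matrix::writeMM(methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix"),
                  path)
  invisible(path)
}
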