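#' Triangle mesh objects
#'
#' A `triangle_mesh` is a closed orientable triangulated surface: an
#' `n x 3` matrix of vertex positions and an `m x 3` integer matrix of
#' vertex indices per face, wound consistently so that face normals point
#' outward from the enclosed volume.
#'
#' @param vertices numeric matrix, one 3D position per row.
#' @param faces integer matrix, one vertex-index triple per row (1-based).
#' @param validate check the closed 2-manifold invariants (every edge
#'   shared by exactly two faces, no degenerate face).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @rdname triangle_mesh
#' @param mesh a `triangle_mesh`.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (min(f) < 1L || max(f) > nrow(v)) stop("face index out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face with repeated vertex index")
  ek <- edge_keys(f)
  tab <- table(ek)
  if (any(tab != 2L))
    stop("mesh is not a closed 2-manifold: ", sum(tab != 2L),
         " edge(s) not shared by exactly 2 faces")
  a <- face_areas(v, f)
  if (any(a <= .Machine$double.eps))
    stop("degenerate (zero-area) face(s): ",
         paste(which(a <= .Machine$double.eps), collapse = ", "))
  invisible(mesh)
}

# canonical undirected edge keys, 3 per face (column-major: edge opposite
# vertex 3 first), encoded as i + (j-1)*n for i < j
edge_keys <- function(faces, n = max(faces)) {
  i <- c(faces[, 1], faces[, 2], faces[, 3])
  j <- c(faces[, 2], faces[, 3], faces[, 1])
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.numeric(lo) + (as.numeric(hi) - 1) * as.numeric(n)
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  cat("  total area:", format(sum(face_areas(x$vertices, x$faces))), "\n")
  invisible(x)
}

#' Geodesic icosphere
#'
#' Builds a sphere by midpoint subdivision of a regular icosahedron, each
#' level projecting the new vertices back to the sphere. Unlike a UV
#' (latitude/longitude) sphere it has no polar clustering, so patterns
#' simulated on it carry no pole artifact.
#'
#' @param subdivisions non-negative integer; the result has
#'   `10 * 4^subdivisions + 2` vertices.
#' @param radius sphere radius.
#' @return a `triangle_mesh` with all vertices at distance `radius` from
#'   the origin and outward winding.
#' @export
make_icosphere <- function(subdivisions = 4L, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mode(f) <- "integer"
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_all(v, f)
    v <- sub$vertices / sqrt(rowSums(sub$vertices^2))
    f <- sub$faces
  }
  triangle_mesh(v * radius, f, validate = FALSE)
}

# uniform 1->4 midpoint subdivision (no projection)
subdivide_all <- function(v, f) {
  n <- nrow(v)
  ek <- edge_keys(f, n)
  ue <- unique(ek)
  midx <- match(ek, ue)            # per (face,edge) slot -> midpoint id
  lo <- (ue - 1) %% n + 1
  hi <- (ue - 1) %/% n + 1
  mids <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
  m <- matrix(midx + n, ncol = 3)  # columns: edge 1-2, 2-3, 3-1
  a <- f[, 1]; b <- f[, 2]; c <- f[, 3]
  ab <- m[, 1]; bc <- m[, 2]; ca <- m[, 3]
  newf <- rbind(cbind(a, ab, ca), cbind(ab, b, bc),
                cbind(ca, bc, c), cbind(ab, bc, ca))
  mode(newf) <- "integer"
  list(vertices = rbind(v, mids), faces = newf)
}

#' Per-face and per-vertex geometry of a mesh
#'
#' Computes everything the finite-element assembly and the deformation
#' step need: face areas, the metric determinant `sqrt(g)` of each
#' triangle's parameterization (the Gram determinant of its edge vectors;
#' identically twice the face area), triangle heights from each vertex,
#' outward unit vertex normals (area-weighted) and barycentric vertex
#' areas (one third of the incident face areas).
#'
#' @param mesh a `triangle_mesh`.
#' @return a list of class `mesh_geometry` with elements `face_area`,
#'   `sqrt_g`, `heights` (m x 3, from vertices 1..3 of each face),
#'   `face_normal`, `vertex_normal`, `vertex_area`, `total_area`.
#' @export
mesh_geometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e3 <- v[f[, 3], , drop = FALSE] - v[f[, 2], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  # sqrt(det g) per triangle from the edge-vector Gram determinant:
  # |e1|^2 |e2|^2 - (e1.e2)^2 = |e1 x e2|^2
  gram <- rowSums(e1^2) * rowSums(e2^2) - rowSums(e1 * e2)^2
  sqrt_g <- sqrt(pmax(gram, 0))
  area <- sqrt_g / 2
  if (any(area <= .Machine$double.eps))
    stop("degenerate (zero-area) face(s): ",
         paste(which(area <= .Machine$double.eps), collapse = ", "))
  # height from vertex i = 2A / length of opposite edge
  heights <- cbind(2 * area / sqrt(rowSums(e3^2)),   # from v1, opposite e(2,3)
                   2 * area / sqrt(rowSums(e2^2)),   # from v2, opposite e(1,3)
                   2 * area / sqrt(rowSums(e1^2)))   # from v3, opposite e(1,2)
  fn <- cr / sqrt(rowSums(cr^2))
  n <- nrow(v)
  # area-weighted vertex normals: cr already has magnitude 2*area
  idx <- c(f[, 1], f[, 2], f[, 3])
  vn <- matrix(0, n, 3)
  s <- rowsum(rbind(cr, cr, cr), idx)
  vn[as.integer(rownames(s)), ] <- s
  vn <- vn / sqrt(rowSums(vn^2))
  va <- tapply_sum(rep(area, 3), idx, n) / 3
  structure(list(face_area = area, sqrt_g = sqrt_g, heights = heights,
                 face_normal = fn, vertex_normal = vn, vertex_area = va,
                 total_area = sum(area)),
            class = "mesh_geometry")
}

# sum `x` into bins `idx` over 1..n (dense, zero-filled)
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# vertex -> vertex adjacency (sparse 0/1 pattern) from the edge set
vertex_adjacency <- function(mesh) {
  f <- mesh$faces; n <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A@x[] <- 1   # duplicates were summed; collapse to 0/1
  A
}

#' Euler characteristic V - E + F
#' @param mesh a `triangle_mesh`.
#' @export
euler_characteristic <- function(mesh) {
  nE <- length(unique(edge_keys(mesh$faces, nrow(mesh$vertices))))
  nrow(mesh$vertices) - nE + nrow(mesh$faces)
}

#' Adaptive midpoint refinement of over-stretched triangles
#'
#' Any face whose area exceeds `threshold_factor` times `reference_area`
#' (the mean face area of the initial mesh) is split into 4 triangles on
#' its edge midpoints. A face adjacent to exactly one refined face is
#' split in 2 across the inserted midpoint; with two or three split
#' edges the face is triangulated compatibly (3 or 4 triangles), so the
#' result is always a closed manifold with no T-junctions. Midpoint
#' subdivision is planar per face, so total surface area is unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param fields optional list of per-vertex numeric vectors, extended to
#'   the inserted midpoints by averaging the two edge endpoints
#'   (consistent with linear finite elements).
#' @param reference_area mean face area of the original (initial) mesh.
#' @param threshold_factor area ratio above which a face is refined
#'   (default 2).
#' @return list with elements `mesh` and `fields`.
#' @export
refine_mesh <- function(mesh, fields = list(), reference_area,
                        threshold_factor = 2) {
  stopifnot(threshold_factor > 0, reference_area > 0)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  area <- face_areas(v, f)
  big <- area > threshold_factor * reference_area
  if (!any(big))
    return(list(mesh = mesh, fields = fields))

  ek <- matrix(edge_keys(f, n), ncol = 3)  # cols: edges 1-2, 2-3, 3-1
  split_keys <- unique(as.vector(ek[big, , drop = FALSE]))
  lo <- as.integer((split_keys - 1) %% n + 1)
  hi <- as.integer((split_keys - 1) %/% n + 1)
  mid_id <- n + seq_along(split_keys)
  v <- rbind(v, (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2)
  fields <- lapply(fields, function(x) c(x, (x[lo] + x[hi]) / 2))

  mid_of <- matrix(match(as.vector(ek), split_keys), ncol = 3)  # NA if unsplit
  out <- vector("list", nrow(f))
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    mab <- mid_of[t, 1]; mbc <- mid_of[t, 2]; mca <- mid_of[t, 3]
    k <- sum(!is.na(c(mab, mbc, mca)))
    if (k == 0L) {
      out[[t]] <- f[t, , drop = FALSE]
    } else if (k == 3L) {
      ab <- mid_id[mab]; bc <- mid_id[mbc]; ca <- mid_id[mca]
      out[[t]] <- rbind(c(a, ab, ca), c(ab, b, bc), c(ca, bc, c),
                        c(ab, bc, ca))
    } else {
      # rotate so the split pattern starts at vertex a
      vs <- c(a, b, c); ms <- c(mab, mbc, mca)
      r <- if (k == 1L) which(!is.na(ms)) else which(is.na(ms)) %% 3 + 1
      rot <- function(x, s) x[((seq_along(x) - 1 + s - 1) %% 3) + 1]
      vs <- rot(vs, r); ms <- rot(ms, r)
      p <- vs[1]; q <- vs[2]; s <- vs[3]
      if (k == 1L) {                       # split edge p-q only
        m1 <- mid_id[ms[1]]
        out[[t]] <- rbind(c(p, m1, s), c(m1, q, s))
      } else {                             # split edges p-q and q-s
        m1 <- mid_id[ms[1]]; m2 <- mid_id[ms[2]]
        out[[t]] <- rbind(c(p, m1, s), c(m1, q, m2), c(m1, m2, s))
      }
    }
  }
  f2 <- do.call(rbind, out)
  mode(f2) <- "integer"
  m2 <- triangle_mesh(v, f2, validate = FALSE)
  ek2 <- edge_keys(f2, nrow(v))
  if (any(table(ek2) != 2L))
    stop("refinement produced a non-manifold mesh")
  list(mesh = m2, fields = fields)
}

#' Neighbor-mean (umbrella) mesh smoothing
#'
#' Each iteration simultaneously replaces every vertex by the arithmetic
#' mean of its 1-ring neighbors. Connectivity is unchanged. Used before
#' inter-mesh interpolation to undo folding.
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of smoothing sweeps (>= 1).
#' @return the smoothed `triangle_mesh`.
#' @export
smooth_mesh <- function(mesh, iterations) {
  stopifnot(iterations >= 1)
  A <- vertex_adjacency(mesh)
  deg <- Matrix::rowSums(A)
  v <- mesh$vertices
  for (i in seq_len(iterations)) v <- as.matrix(A %*% v) / deg
  triangle_mesh(v, mesh$faces, validate = FALSE)
}

#' Transfer a per-vertex field between deformed meshes
#'
#' Both meshes are smoothed back toward a sphere (`smooth_mesh`), centered
#' on their centroid and radially projected to the unit sphere; each
#' target vertex then takes the barycentric interpolation of the field on
#' the source face its direction falls in. Valid for meshes that are
#' deformations/refinements of a common sphere and star-shaped after
#' smoothing.
#'
#' @param source_mesh,target_mesh `triangle_mesh` objects.
#' @param field numeric per-vertex field on `source_mesh`.
#' @param smoothing_iterations sweeps applied to both meshes before
#'   projection (default 100; 0 skips smoothing).
#' @return numeric per-vertex field on `target_mesh`.
#' @export
resample_field <- function(source_mesh, field, target_mesh,
                           smoothing_iterations = 100) {
  stopifnot(length(field) == nrow(source_mesh$vertices))
  if (nrow(source_mesh$vertices) == 0) stop("empty source mesh")
  sm <- if (smoothing_iterations > 0)
    smooth_mesh(source_mesh, smoothing_iterations) else source_mesh
  tm <- if (smoothing_iterations > 0)
    smooth_mesh(target_mesh, smoothing_iterations) else target_mesh
  su <- unit_project(sm$vertices)
  tu <- unit_project(tm$vertices)
  interp_on_sphere(su, sm$faces, field, tu)
}

unit_project <- function(v) {
  v <- sweep(v, 2, colMeans(v))
  r <- sqrt(rowSums(v^2))
  if (any(r <= 0)) stop("degenerate vertex at centroid")
  v / r
}

# barycentric interpolation of `field` from unit-sphere mesh (sv, faces)
# at unit directions `td` (central projection onto candidate faces)
interp_on_sphere <- function(sv, faces, field, td) {
  # faces incident to each source vertex
  n <- nrow(sv)
  finc <- split(rep(seq_len(nrow(faces)), 3), as.vector(faces))
  # nearest source vertex per target (block the dot-product matrix)
  out <- numeric(nrow(td))
  blk <- 2048L
  for (s0 in seq(1, nrow(td), by = blk)) {
    idx <- s0:min(s0 + blk - 1L, nrow(td))
    dots <- td[idx, , drop = FALSE] %*% t(sv)
    nearest <- max.col(dots, ties.method = "first")
    for (ii in seq_along(idx)) {
      d <- td[idx[ii], ]
      cand <- finc[[as.character(nearest[ii])]]
      best_w <- NULL; best_face <- NA_integer_; best_min <- -Inf
      for (ft in cand) {
        tri <- faces[ft, ]
        Amat <- t(sv[tri, , drop = FALSE])      # 3x3, columns = corners
        w <- tryCatch(solve(Amat, d), error = function(e) NULL)
        if (is.null(w)) next
        sw <- sum(w)
        if (sw <= 0) next
        w <- w / sw
        mn <- min(w)
        if (mn > best_min) { best_min <- mn; best_w <- w; best_face <- ft }
        if (mn >= -1e-9) break
      }
      if (is.null(best_w)) {              # fall back to nearest vertex value
        out[idx[ii]] <- field[nearest[ii]]
      } else {
        w <- pmax(best_w, 0); w <- w / sum(w)
        out[idx[ii]] <- sum(w * field[faces[best_face, ]])
      }
    }
  }
  out
}
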