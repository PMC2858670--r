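#' Discrete mean curvature map
#'
#' Mean curvature via the discrete mean-curvature normal: the stiffness
#' operator applied to the three coordinate functions gives, per vertex,
#' a vector of magnitude `2 A_i |H_i|`; dividing by twice the vertex
#' area yields `|H|`, and the sign is positive where the vector points
#' along the outward vertex normal (locally convex, gyral) and negative
#' where it points inward (concave, sulcal). A sphere of radius `R`
#' thus gets `+1/R` everywhere. The normalizing vertex area is the
#' circumcentric (Voronoi) area derived from the cotangent weights —
#' markedly more accurate than the barycentric area at irregular
#' vertices — with a barycentric fallback wherever obtuse triangles
#' drive the Voronoi area non-positive.
#'
#' @param mesh a `triangle_mesh`.
#' @param geometry its `mesh_geometry`.
#' @param fem optional `fem_system` on the same mesh (reuses its
#'   stiffness matrix).
#' @return numeric per-vertex mean curvature (1/length).
#' @export
mean_curvature <- function(mesh, geometry = mesh_geometry(mesh),
                           fem = NULL) {
  if (any(geometry$vertex_area <= 0)) stop("zero vertex area")
  K <- if (is.null(fem)) assemble_stiffness(mesh, geometry)
       else fem$stiffness
  area <- voronoi_vertex_area(mesh, K)
  bad <- !is.finite(area) | area <= 0
  area[bad] <- geometry$vertex_area[bad]
  Kx <- as.matrix(K %*% mesh$vertices)
  mag <- sqrt(rowSums(Kx^2)) / (2 * area)
  sgn <- sign(rowSums(Kx * geometry$vertex_normal))
  sgn[sgn == 0] <- 1
  sgn * mag
}

# circumcentric vertex area A_i = (1/8) sum_j (cot a + cot b) |xi - xj|^2,
# read off the stiffness off-diagonals K_ij = -(cot a + cot b)/2
voronoi_vertex_area <- function(mesh, K) {
  n <- nrow(mesh$vertices)
  Kt <- methods::as(methods::as(K, "generalMatrix"), "TsparseMatrix")
  off <- Kt@i != Kt@j
  i <- Kt@i[off] + 1L; j <- Kt@j[off] + 1L
  w <- -2 * Kt@x[off]
  d2 <- rowSums((mesh$vertices[i, , drop = FALSE] -
                   mesh$vertices[j, , drop = FALSE])^2)
  tapply_sum(w * d2 / 8, i, n)
}

#' Binary fold (sulcus) indicator
#'
#' 1 where the curvature is strictly negative, 0 elsewhere.
#'
#' @param curv per-vertex curvature map.
#' @return integer vector of 0/1.
#' @export
threshold_map <- function(curv) {
  as.integer(curv < 0)
}

#' Segment folds by region growing
#'
#' Folds are the connected components of the indicator-1 vertex set
#' under mesh-edge adjacency. Starting from the lowest-index unvisited
#' seed, a breadth-first region is grown over negative-curvature
#' vertices; the procedure repeats until no seeds remain, so the result
#' is independent of seed order.
#'
#' @param bmap 0/1 per-vertex indicator ([threshold_map()]).
#' @param mesh the `triangle_mesh` the map lives on.
#' @return list with `labels` (per-vertex component id, 0 = non-fold)
#'   and `n_folds`.
#' @export
segment_folds <- function(bmap, mesh) {
  n <- nrow(mesh$vertices)
  stopifnot(length(bmap) == n)
  adj <- adjacency_list(mesh)
  labels <- integer(n)
  lab <- 0L
  active <- bmap != 0L
  for (seed in seq_len(n)) {
    if (!active[seed] || labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    while (length(queue)) {
      nb <- unique(unlist(adj[queue], use.names = FALSE))
      nb <- nb[active[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- nb
    }
  }
  list(labels = labels, n_folds = lab)
}

adjacency_list <- function(mesh) {
  f <- mesh$faces; n <- nrow(mesh$vertices)
  i <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  j <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  keep <- !duplicated(as.numeric(i) + (as.numeric(j) - 1) * n)
  unname(split(j[keep], factor(i[keep], levels = seq_len(n))))
}

#' Fold count at every snapshot of a simulation
#'
#' @param sim a `cortical_sim`.
#' @return data.frame with columns `time` and `count`.
#' @export
fold_count_series <- function(sim) {
  counts <- vapply(sim$snapshots, function(s) {
    curv <- if (is.null(s$curvature)) mean_curvature(s$mesh) else s$curvature
    segment_folds(threshold_map(curv), s$mesh)$n_folds
  }, integer(1))
  data.frame(time = sim$times, count = counts)
}

#' Temporal fold-stability map
#'
#' Each snapshot's binary fold map is transferred to a common reference
#' mesh ([resample_field()] on smoothed, unit-projected meshes),
#' re-binarized at 0.5, and averaged over snapshots. The value at a
#' vertex is the proportion of the simulated interval during which that
#' position lies in a fold; it stays below 1 whenever an initial
#' foldless phase exists.
#'
#' @param sim a `cortical_sim` with at least one snapshot.
#' @param reference_mesh the common mesh to aggregate on (default: the
#'   final, finest mesh of the trace).
#' @param smoothing_iterations smoothing sweeps before interpolation.
#' @return per-vertex values in `[0, 1]` on `reference_mesh`.
#' @export
time_average_map <- function(sim, reference_mesh = sim$mesh,
                             smoothing_iterations = 100) {
  if (length(sim$snapshots) == 0) stop("empty trace")
  acc <- numeric(nrow(reference_mesh$vertices))
  for (s in sim$snapshots) {
    curv <- if (is.null(s$curvature)) mean_curvature(s$mesh) else s$curvature
    b <- threshold_map(curv)
    r <- resample_field(s$mesh, as.numeric(b), reference_mesh,
                        smoothing_iterations)
    acc <- acc + as.integer(r > 0.5)
  }
  acc / length(sim$snapshots)
}

#' Ensemble reproducibility map
#'
#' Sum of binary fold maps over realizations, in percent: `S = 100 *
#' mean(bmaps)` per vertex. High values flag positions folded in most
#' realizations.
#'
#' @param bmaps list of 0/1 per-vertex maps on a common reference mesh.
#' @return per-vertex values in `[0, 100]`.
#' @export
ensemble_map <- function(bmaps) {
  if (length(bmaps) == 0) stop("empty map list")
  len <- unique(vapply(bmaps, length, integer(1)))
  if (length(len) != 1) stop("maps have mismatched lengths")
  100 * Reduce(`+`, bmaps) / length(bmaps)
}

#' Elongation of fold components
#'
#' For each fold component, the graph diameter (in edges, over the
#' component's induced subgraph) divided by the square root of its
#' vertex count. Stripe-like folds score high, compact spots low.
#'
#' @param seg a [segment_folds()] result.
#' @param mesh the mesh.
#' @return numeric vector, one elongation per component.
#' @export
fold_elongation <- function(seg, mesh) {
  if (seg$n_folds == 0) return(numeric(0))
  f <- mesh$faces
  el <- numeric(seg$n_folds)
  g_edges <- cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
  for (comp in seq_len(seg$n_folds)) {
    vs <- which(seg$labels == comp)
    if (length(vs) == 1L) { el[comp] <- 0; next }
    keep <- seg$labels[g_edges[, 1]] == comp & seg$labels[g_edges[, 2]] == comp
    sub <- g_edges[keep, , drop = FALSE]
    idx <- match(sub, vs)
    g <- igraph::graph_from_edgelist(matrix(idx, ncol = 2), directed = FALSE)
    g <- igraph::simplify(g)
    if (igraph::vcount(g) < length(vs))
      g <- igraph::add_vertices(g, length(vs) - igraph::vcount(g))
    el[comp] <- igraph::diameter(g, directed = FALSE) / sqrt(length(vs))
  }
  el
}

#' Classify the folding regime of a finished simulation
#'
#' On the final snapshot: if the spatial variance of `v` is below
#' `var_tol` the run never patterned — the homogeneous, smooth-surface
#' regime (lissencephaly-like). Otherwise folds are segmented and their
#' mean elongation decides between stripe-like patterning
#' (normal-gyrification-like) at `e >= e_threshold` and compact
#' spot-like patterning (polymicrogyria-like) below it.
#'
#' @param sim a `cortical_sim`.
#' @param e_threshold stripes-vs-spots elongation cut (default 2).
#' @param var_tol variance cut for homogeneity (default 1e-6).
#' @return list with `regime` (one of `"homogeneous"`, `"stripes"`,
#'   `"spots"`), `pathology_analogue`, `n_folds`, `v_variance`,
#'   `mean_elongation`.
#' @export
classify_regime <- function(sim, e_threshold = 2, var_tol = 1e-6) {
  s <- sim$snapshots[[length(sim$snapshots)]]
  vvar <- stats::var(s$v)
  curv <- if (is.null(s$curvature)) mean_curvature(s$mesh) else s$curvature
  seg <- segment_folds(threshold_map(curv), s$mesh)
  if (vvar < var_tol) {
    return(list(regime = "homogeneous",
                pathology_analogue = "lissencephaly",
                n_folds = seg$n_folds, v_variance = vvar,
                mean_elongation = NA_real_))
  }
  el <- fold_elongation(seg, s$mesh)
  me <- if (length(el)) mean(el) else 0
  if (me >= e_threshold)
    list(regime = "stripes", pathology_analogue = "normal",
         n_folds = seg$n_folds, v_variance = vvar, mean_elongation = me)
  else
    list(regime = "spots", pathology_analogue = "polymicrogyria",
         n_folds = seg$n_folds, v_variance = vvar, mean_elongation = me)
}

#' Count segments of the main fold
#'
#' Restricts a binary fold map to the tube of vertices around the seeded
#' great-circle band and counts connected components there — the number
#' of parts the main fold is broken into.
#'
#' @param bmap 0/1 per-vertex map on `mesh`.
#' @param mesh the reference `triangle_mesh` (an undeformed sphere).
#' @param band_half_width angular half-width (radians) of the tube
#'   around the equatorial great circle.
#' @param margin extra angular margin added to the tube.
#' @return integer segment count.
#' @export
main_fold_segments <- function(bmap, mesh, band_half_width = 0.15,
                               margin = 0.1) {
  r <- sqrt(rowSums(mesh$vertices^2))
  lat <- asin(pmax(-1, pmin(1, mesh$vertices[, 3] / r)))
  tube <- abs(lat) <= band_half_width + margin
  segment_folds(as.integer(bmap != 0 & tube), mesh)$n_folds
}
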