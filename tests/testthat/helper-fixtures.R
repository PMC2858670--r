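# Shared fixtures built in code.

# single equilateral triangle of side 1 closed into a degenerate-free
# tetrahedron is overkill; for element-level checks we call the assembly
# internals on an open one-triangle "mesh" (no manifold validation).
one_triangle <- function(p1 = c(0, 0, 0), p2 = c(1, 0, 0),
                         p3 = c(0.5, sqrt(3) / 2, 0)) {
  triangle_mesh(rbind(p1, p2, p3), rbind(c(1, 2, 3)), validate = FALSE)
}

regular_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangle_mesh(v, f)
}

# a sphere with a spherical cap dented inward around direction `dir`
dented_sphere <- function(subdivisions = 3, cap_angle = 0.5, depth = 0.4,
                          dir = c(0, 0, 1)) {
  m <- make_icosphere(subdivisions)
  d <- dir / sqrt(sum(dir^2))
  ang <- acos(pmax(-1, pmin(1, m$vertices %*% d)))
  w <- pmax(0, cos(pi / 2 * ang / cap_angle))^2
  w[ang > cap_angle] <- 0
  r <- 1 - depth * w
  triangle_mesh(m$vertices * as.numeric(r), m$faces)
}

# brute-force connected components of the 1-set of `bmap` via igraph
oracle_components <- function(bmap, mesh) {
  n <- nrow(mesh$vertices)
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
             cbind(f[, 3], f[, 1]))
  g <- igraph::simplify(igraph::graph_from_edgelist(e, directed = FALSE))
  keep <- which(bmap != 0)
  if (length(keep) == 0) return(0L)
  sub <- igraph::induced_subgraph(g, keep)
  igraph::components(sub)$no
}

# dense brute-force P1 mass/stiffness assembly by per-face exact integrals
dense_assembly <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces; n <- nrow(v)
  M <- matrix(0, n, n); K <- matrix(0, n, n)
  for (t in seq_len(nrow(f))) {
    tri <- f[t, ]
    p <- v[tri, , drop = FALSE]
    e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    A <- 0.5 * sqrt(sum(cr^2))
    Me <- A / 12 * (matrix(1, 3, 3) + diag(3))
    # gradients of hat functions from opposite edges rotated in-plane
    nrm <- cr / (2 * A)
    grads <- matrix(0, 3, 3)
    opp <- list(p[3, ] - p[2, ], p[1, ] - p[3, ], p[2, ] - p[1, ])
    for (k in 1:3) {
      ek <- opp[[k]]
      grads[k, ] <- c(nrm[2] * ek[3] - nrm[3] * ek[2],
                      nrm[3] * ek[1] - nrm[1] * ek[3],
                      nrm[1] * ek[2] - nrm[2] * ek[1]) / (2 * A)
    }
    Ke <- A * grads %*% t(grads)
    M[tri, tri] <- M[tri, tri] + Me
    K[tri, tri] <- K[tri, tri] + Ke
  }
  list(M = M, K = K)
}

default_test_config <- function(...) {
  experiment_config(subdivisions = 2L, horizon = 60L, snapshot_every = 20L,
                    Du = 2e-3, Dv = 1e-3, ...)
}
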