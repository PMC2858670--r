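test_that("icosphere has the expected counts, radius and area", {
  m0 <- make_icosphere(0)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m3 <- make_icosphere(3)
  expect_equal(nrow(m3$vertices), 10 * 4^3 + 2)
  expect_equal(nrow(m3$faces), 1280L)
  m4 <- make_icosphere(4, radius = 1)
  expect_true(all(abs(sqrt(rowSums(m4$vertices^2)) - 1) < 1e-12))
  g4 <- mesh_geometry(m4)
  expect_lt(abs(g4$total_area - 4 * pi) / (4 * pi), 0.01)
  expect_equal(euler_characteristic(m4), 2L)
  expect_silent(validate_mesh(m4))
})

test_that("geometry cache satisfies its identities", {
  tri <- one_triangle()
  g <- mesh_geometry(tri)
  expect_equal(g$face_area, sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(as.numeric(g$heights), rep(sqrt(3) / 2, 3),
               tolerance = 1e-12)
  m <- dented_sphere(3)
  gm <- mesh_geometry(m)
  expect_equal(gm$sqrt_g, 2 * gm$face_area, tolerance = 1e-12)
  expect_equal(sum(gm$vertex_area), gm$total_area, tolerance = 1e-12)
  expect_equal(rowSums(gm$vertex_normal^2),
               rep(1, nrow(m$vertices)), tolerance = 1e-10)
  # radial normals on the sphere, within a degree
  m4 <- make_icosphere(4)
  g4 <- mesh_geometry(m4)
  cosdev <- rowSums(g4$vertex_normal * m4$vertices)
  expect_true(all(cosdev > cos(pi / 180)))
  # degenerate face errors with its index
  bad <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       rbind(c(1, 2, 3)), validate = FALSE)
  expect_error(mesh_geometry(bad), "degenerate")
})

test_that("manifold validation rejects broken meshes", {
  m <- make_icosphere(1)
  expect_error(triangle_mesh(m$vertices, m$faces[-1, , drop = FALSE]),
               "manifold")
  f <- m$faces; f[1, 2] <- f[1, 1]
  expect_error(triangle_mesh(m$vertices, f), "repeated")
})

test_that("refining one over-threshold icosahedron face gives 4 + 3x2 faces", {
  m <- make_icosphere(0)
  g <- mesh_geometry(m)
  ref_area <- mean(g$face_area)
  # stretch the three corners of face 1 just enough that only it crosses
  v <- m$vertices
  tri <- m$faces[1, ]
  v[tri, ] <- v[tri, ] * 1.45
  m2 <- triangle_mesh(v, m$faces)
  a2 <- mesh_geometry(m2)$face_area
  expect_equal(sum(a2 > 2 * ref_area), 1L)
  out <- refine_mesh(m2, fields = list(u = seq_len(12) * 1.0),
                     reference_area = ref_area)
  expect_equal(nrow(out$mesh$faces), 26L)     # 20 - 4 + 4 + 3*2 = 26
  expect_equal(nrow(out$mesh$vertices), 15L)  # 3 midpoints inserted
  expect_equal(euler_characteristic(out$mesh), 2L)
  # area is exactly preserved
  expect_equal(mesh_geometry(out$mesh)$total_area,
               mesh_geometry(m2)$total_area, tolerance = 1e-14)
  # midpoint fields are edge-endpoint means of face 1's vertex pairs
  expect_equal(length(out$fields$u), 15L)
  expect_setequal(out$fields$u[13:15],
                  c(mean(tri[1:2]), mean(tri[2:3]), mean(tri[c(1, 3)])))
})

test_that("refinement is a no-op below threshold and conserves area above", {
  m <- make_icosphere(2)
  g <- mesh_geometry(m)
  out <- refine_mesh(m, reference_area = mean(g$face_area))
  expect_identical(out$mesh$faces, m$faces)
  # grow the whole mesh so every face refines (all-neighbors case)
  m2 <- triangle_mesh(m$vertices * 2, m$faces)
  out2 <- refine_mesh(m2, reference_area = mean(g$face_area))
  expect_equal(nrow(out2$mesh$faces), 4 * nrow(m$faces))
  expect_equal(mesh_geometry(out2$mesh)$total_area,
               mesh_geometry(m2)$total_area, tolerance = 1e-12)
  expect_equal(euler_characteristic(out2$mesh), 2L)
  expect_silent(validate_mesh(out2$mesh))
})

test_that("smoothing a sphere keeps it spherical and shrinks folded meshes", {
  m <- make_icosphere(3)
  s1 <- smooth_mesh(m, 1)
  r <- sqrt(rowSums(s1$vertices^2))
  # vertices move radially inward, uniformly within each symmetry orbit;
  # across orbits the spread stays tiny
  expect_true(all(r < 1))
  expect_lt((max(r) - min(r)) / mean(r), 5e-3)
  # composition: 1 iteration twice equals 2 at once
  expect_equal(smooth_mesh(smooth_mesh(m, 1), 1)$vertices,
               smooth_mesh(m, 2)$vertices, tolerance = 1e-14)
  expect_error(smooth_mesh(m, 0))
  # monotone area contraction on a folded fixture
  d <- dented_sphere(3)
  areas <- numeric(20)
  cur <- d
  for (i in 1:20) {
    cur <- smooth_mesh(cur, 1)
    areas[i] <- mesh_geometry(cur)$total_area
  }
  expect_true(all(diff(c(mesh_geometry(d)$total_area, areas)) < 0))
})

test_that("field resampling is exact for constants and accurate for linears", {
  src <- make_icosphere(4)
  tgt <- make_icosphere(3)
  cst <- resample_field(src, rep(2.5, nrow(src$vertices)), tgt,
                        smoothing_iterations = 5)
  expect_equal(cst, rep(2.5, nrow(tgt$vertices)), tolerance = 1e-12)
  # a linear-in-z field survives the transfer to < 0.01
  fz <- src$vertices[, 3]
  rz <- resample_field(src, fz, tgt, smoothing_iterations = 0)
  expect_lt(max(abs(rz - tgt$vertices[, 3])), 0.01)
  # identity transfer
  self <- resample_field(src, fz, src, smoothing_iterations = 0)
  expect_lt(max(abs(self - fz)), 1e-9)
})
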