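test_that("Gray-Scott kinetics: hand values and fixed points", {
  p <- gray_scott_params(F = 0.04, k = 0.06)
  # homogeneous trivial state
  rt <- reaction_terms(1, 0, p)
  expect_equal(rt$du, 0)
  expect_equal(rt$dv, 0)
  # hand evaluation of -uv^2 + F(1-u), uv^2 - (F+k)v
  rt2 <- reaction_terms(0.5, 0.25, p)
  expect_equal(rt2$du, -0.01125, tolerance = 1e-14)
  expect_equal(rt2$dv, 0.00625, tolerance = 1e-14)
  # every reported equilibrium annihilates the kinetics
  for (pp in list(p, gray_scott_params(F = 0.05, k = 0.05),
                  gray_scott_params(F = 0.062, k = 0.061))) {
    for (e in homogeneous_equilibria(pp)) {
      r <- reaction_terms(e[["u"]], e[["v"]], pp)
      expect_lt(abs(r$du), 1e-12)
      expect_lt(abs(r$dv), 1e-12)
    }
  }
})

test_that("nontrivial equilibria appear exactly when F >= 4(F+k)^2", {
  # (0.04, 0.06): discriminant exactly zero -> degenerate double root
  expect_equal(0.04 - 4 * (0.04 + 0.06)^2, 0)
  eq <- homogeneous_equilibria(gray_scott_params(F = 0.04, k = 0.06))
  expect_length(eq, 2)
  # (0.02, 0.06): negative discriminant, trivial state only
  expect_lt(0.02 - 4 * (0.02 + 0.06)^2, 0)
  eq2 <- homogeneous_equilibria(gray_scott_params(F = 0.02, k = 0.06))
  expect_length(eq2, 1)
  expect_equal(eq2[[1]], c(u = 1, v = 0))
  # (0.05, 0.05): two distinct nontrivial roots
  eq3 <- homogeneous_equilibria(gray_scott_params(F = 0.05, k = 0.05))
  expect_length(eq3, 3)
})

test_that("dilution of a uniformly rescaled sphere matches 2 rdot / r", {
  m <- make_icosphere(3)
  g1 <- mesh_geometry(m)
  m2 <- triangle_mesh(m$vertices * 1.001, m$faces, validate = FALSE)
  g2 <- mesh_geometry(m2)
  d <- dilution_field(g1, g2, dt = 1, faces = m$faces)
  expect_equal(d, rep((1.001^2 - 1) / 1.001^2, length(d)),
               tolerance = 1e-12)
  expect_lt(max(abs(d - 2 * 0.001)) / (2 * 0.001), 0.01)
  # static mesh: zero field
  expect_equal(dilution_field(g1, g1, 1, m$faces),
               rep(0, nrow(m$vertices)))
  # mismatched connectivity errors
  g3 <- mesh_geometry(make_icosphere(2))
  expect_error(dilution_field(g3, g1, 1, m$faces), "connectivity")
})

test_that("uniform equilibrium is preserved by the IMEX step", {
  m <- make_icosphere(2)
  fem <- fem_system(m)
  n <- nrow(m$vertices)
  st <- morphogen_state(rep(1, n), rep(0, n))
  p <- gray_scott_params()
  for (i in 1:50) st <- step_fields(st, p, fem)
  expect_lt(max(abs(st$u - 1)), 1e-10)
  expect_equal(st$v, rep(0, n))
  expect_equal(st$time, 50)
})

test_that("with no diffusion the step reduces to the pointwise recurrence", {
  m <- make_icosphere(2)
  fem <- fem_system(m, lumped = TRUE)
  n <- nrow(m$vertices)
  set.seed(7)
  u0 <- runif(n, 0.3, 1); v0 <- runif(n, 0, 0.5)
  # vanishing diffusion decouples vertices; lumped mass then cancels
  p <- gray_scott_params(F = 0.04, k = 0.06, Du = 1e-300, Dv = 1e-300,
                         dt = 0.7)
  st <- step_fields(morphogen_state(u0, v0), p, fem)
  u1 <- (u0 + 0.7 * 0.04) / (1 + 0.7 * (v0^2 + 0.04))
  v1 <- (v0 + 0.7 * u0 * v0^2) / (1 + 0.7 * (0.04 + 0.06))
  expect_equal(st$u, u1, tolerance = 1e-12)
  expect_equal(st$v, v1, tolerance = 1e-12)
})

test_that("pure diffusion conserves total mass over 1000 steps", {
  m <- make_icosphere(3)
  fem <- fem_system(m)
  n <- nrow(m$vertices)
  set.seed(11)
  u <- runif(n)
  m0 <- sum(fem$mass %*% u)
  # no reaction: u satisfies a pure heat equation when v = 0 and the
  # feed/removal terms are switched off via F -> 0 limit
  p <- structure(list(F = 0, k = 0, Du = 2e-3, Dv = 1e-3, dt = 1),
                 class = "gray_scott_params")
  st <- morphogen_state(u, numeric(n))
  for (i in 1:1000) st <- step_fields(st, p, fem)
  m1 <- sum(fem$mass %*% st$u)
  expect_lt(abs(m1 - m0) / abs(m0), 1e-8)
  # and the field relaxes toward its mean, staying bounded
  expect_lt(max(st$u) - min(st$u), max(u) - min(u))
})

test_that("the IMEX scheme is first order in dt", {
  m <- make_icosphere(2)   # 162-vertex sphere
  fem <- fem_system(m)
  n <- nrow(m$vertices)
  set.seed(3)
  u0 <- runif(n, 0.4, 1); v0 <- runif(n, 0, 0.4)
  advance <- function(dt, nsteps) {
    p <- gray_scott_params(F = 0.04, k = 0.06, Du = 2e-3, Dv = 1e-3,
                           dt = dt)
    st <- morphogen_state(u0, v0)
    for (i in seq_len(nsteps)) st <- step_fields(st, p, fem)
    c(st$u, st$v)
  }
  ref <- advance(1 / 256, 256)   # fine reference over unit time
  e1 <- max(abs(advance(1 / 4, 4) - ref))
  e2 <- max(abs(advance(1 / 8, 8) - ref))
  order <- log2(e1 / e2)
  expect_gt(order, 0.8)
  expect_lt(order, 1.2)
})

test_that("morphogen state rejects non-finite fields", {
  expect_error(morphogen_state(c(1, NaN), c(0, 0)), "finite")
  expect_error(morphogen_state(c(1, 1), c(0, Inf)), "finite")
})

test_that("seeded perturbations pattern or decay as the (F,k) regime dictates", {
  m <- make_icosphere(3)
  static <- deformation_params(alpha = 0, snapshot_every = 750L)
  # normal-regime pair: the perturbation settles into a sustained pattern
  sim_p <- run_simulation(m, initial_condition_line(m, 0.1, 1),
                          gray_scott_params(F = 0.04, k = 0.06),
                          static, horizon = 1500L,
                          record_curvature = FALSE)
  expect_gt(stats::var(sim_p$state$v), 1e-3)
  expect_true(all(sim_p$state$u >= -1e-6 & sim_p$state$u <= 1 + 1e-6))
  expect_true(all(sim_p$state$v >= -1e-6 & sim_p$state$v <= 1 + 1e-6))
  # lissencephaly pair: return to spatial homogeneity
  sim_h <- run_simulation(m, initial_condition_line(m, 0.1, 1),
                          gray_scott_params(F = 0.05, k = 0.05),
                          static, horizon = 1500L,
                          record_curvature = FALSE)
  expect_lt(stats::var(sim_h$state$v), 1e-8)
})
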