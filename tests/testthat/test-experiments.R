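test_that("seeded-line initial condition is a reproducible two-level field", {
  m <- make_icosphere(3)
  st <- initial_condition_line(m, noise_amplitude = 0, seed = 1)
  expect_length(unique(st$u), 2L)
  expect_length(unique(st$v), 2L)
  expect_setequal(unique(st$u), c(1, 0.5))
  expect_setequal(unique(st$v), c(0, 0.25))
  # same seed -> identical; different seed -> different noise
  a <- initial_condition_line(m, 0.05, seed = 7)
  b <- initial_condition_line(m, 0.05, seed = 7)
  c <- initial_condition_line(m, 0.05, seed = 8)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  expect_false(identical(a$u, c$u))
  # band population tracks the analytic zone fraction sin(half-width)
  m4 <- make_icosphere(4)
  st4 <- initial_condition_line(m4, 0, 1)
  frac <- mean(st4$v > 0)
  expect_gt(frac, 0.05)
  expect_lt(abs(frac - sin(0.15)), 0.01)
})

test_that("configurations round-trip through YAML", {
  cfg <- experiment_config(subdivisions = 2L, F = 0.033, horizon = 123L,
                           noise_amplitude = 0.07, seed = 42L,
                           F_grid = c(0.02, 0.05), k_grid = c(0.06))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("identical seeds make run_configured fully deterministic", {
  cfg <- default_test_config()
  s1 <- run_configured(cfg)
  s2 <- run_configured(cfg)
  expect_identical(s1$state$u, s2$state$u)
  expect_identical(s1$state$v, s2$state$v)
  expect_identical(s1$mesh$vertices, s2$mesh$vertices)
})

test_that("a duplicate-seed mini ensemble gives an all-or-nothing S map", {
  cfg <- default_test_config(ensemble_size = 2L, alpha = 0.002,
                             smoothing_iterations = 10L)
  # force both realizations onto the same seed by zeroing the noise
  cfg$noise_amplitude <- 0
  ens <- run_ensemble(cfg)
  expect_true(all(ens$S %in% c(0, 100)))
  expect_length(ens$bmaps, 2L)
  expect_equal(dim(ens$average_surface$vertices),
               dim(ens$reference_mesh$vertices))
})

test_that("equilibrium-initialized ensemble has an identically zero S map", {
  cfg <- default_test_config(ensemble_size = 2L, alpha = 0,
                             smoothing_iterations = 5L)
  cfg$band_u <- 1; cfg$band_v <- 0; cfg$noise_amplitude <- 0
  ens <- run_ensemble(cfg)
  expect_true(all(ens$S == 0))
  expect_equal(ens$fold_counts, c(0L, 0L))
  expect_equal(ens$main_fold_segments, c(0L, 0L))
})

test_that("a degenerate 1x1 phase diagram classifies a uniform run", {
  cfg <- default_test_config(F_grid = 0.04, k_grid = 0.06)
  cfg$band_u <- 1; cfg$band_v <- 0; cfg$noise_amplitude <- 0
  pd <- phase_diagram(cfg)
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$regime, "homogeneous")
})

test_that("the default phase-diagram grid spans 28 couples incl. Fig pairs", {
  cfg <- experiment_config()
  grid <- expand.grid(F = cfg$F_grid, k = cfg$k_grid)
  expect_equal(nrow(grid), 28L)
  for (fk in list(c(0.04, 0.06), c(0.03, 0.06), c(0.05, 0.05))) {
    expect_true(any(abs(grid$F - fk[1]) < 1e-12 &
                      abs(grid$k - fk[2]) < 1e-12))
  }
})

test_that("cli drives make-config, simulate and analyze end to end", {
  dir <- withr::local_tempdir()
  cfgp <- file.path(dir, "cfg.yaml")
  expect_equal(suppressMessages(cli(c("make-config", cfgp))), 0L)
  cfg <- read_config(cfgp)
  cfg$subdivisions <- 2L; cfg$horizon <- 40L; cfg$snapshot_every <- 20L
  cfg$Du <- 2e-3; cfg$Dv <- 1e-3
  write_config(cfg, cfgp)
  out1 <- file.path(dir, "trace")
  expect_equal(suppressMessages(cli(c("simulate", cfgp, out1))), 0L)
  expect_true(file.exists(file.path(out1, "index.json")))
  expect_true(file.exists(file.path(out1, "final.ply")))
  # determinism: same config and seed -> bit-identical stored fields
  out2 <- file.path(dir, "trace2")
  expect_equal(suppressMessages(cli(c("simulate", cfgp, out2))), 0L)
  last <- max(list.files(out1, pattern = "_u.txt$"))
  expect_identical(readLines(file.path(out1, last)),
                   readLines(file.path(out2, last)))
  # analyze a stored trace
  outa <- file.path(dir, "analysis")
  expect_equal(suppressMessages(cli(c("analyze", out1, outa))), 0L)
  expect_true(file.exists(file.path(outa, "curvature.txt")))
  expect_true(file.exists(file.path(outa, "time_average_A.txt")))
  A <- read_vertex_map(file.path(outa, "time_average_A.txt"))
  expect_true(all(A >= 0 & A <= 1))
  # bad invocations exit nonzero
  expect_equal(suppressMessages(cli(c("simulate", "/nope.yaml", dir))), 1L)
  expect_equal(suppressMessages(cli("frobnicate")), 1L)
  expect_equal(suppressMessages(cli(character(0))), 1L)
})

test_that("a seeded line is more reproducible than pure equilibrium noise", {
  # same noise, same seeds; one ensemble seeds the line, the other only
  # perturbs the homogeneous equilibrium everywhere
  line <- experiment_config(ensemble_size = 3L)
  ens_line <- run_ensemble(line)
  unif <- experiment_config(ensemble_size = 3L, band_half_width = pi,
                            band_u = 1, band_v = 0)
  ens_unif <- run_ensemble(unif)
  expect_gt(max(ens_line$S), max(ens_unif$S))
  expect_equal(max(ens_unif$S), 0)
})
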