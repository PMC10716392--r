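test_that("single-atom amplitude equals the form factor for every direction", {
  cfg <- fixed_config(c(0, 0, 0), species = "W")
  qv <- generate_q_directions(8, seed = 1) * 0.7
  a <- sas_amplitude(cfg, NULL, qv, "SAXS")
  expect_equal(Mod(a), rep(10, 8), tolerance = 1e-12)
  ## and the D2O pseudo-water value in neutron units
  a2 <- sas_amplitude(cfg, NULL, qv, "SANS_D2O")
  expect_equal(Mod(a2), rep(19.145, 8), tolerance = 1e-9)
})

test_that("translation changes only the phase of the amplitude", {
  pos <- matrix(runif(15, -0.5, 0.5), ncol = 3)
  cfg <- fixed_config(pos)
  cfg2 <- fixed_config(sweep(pos, 2, c(1.3, -0.7, 2.1), `+`))
  qv <- generate_q_directions(20, seed = 2) * 1.4
  expect_equal(Mod(sas_amplitude(cfg, NULL, qv)),
               Mod(sas_amplitude(cfg2, NULL, qv)), tolerance = 1e-9)
})

test_that("dimer orientational average matches the closed form", {
  d <- 0.5
  cfg <- fixed_config(rbind(c(0, 0, 0), c(0, 0, d)))
  q <- c(0.4, 1, 2, 3)
  est <- avg_intensity(cfg, q, n_dir = 200)
  f <- species_table()$electrons[species_table()$label == "C"]
  closed <- f^2 * 2 * (1 + sin(q * d) / (q * d))
  expect_equal(est, closed, tolerance = 0.01)
})

test_that("the C++ Debye kernel agrees with a direct R double sum", {
  set.seed(8)
  pos <- matrix(runif(18, -0.4, 0.4), ncol = 3)
  cfg <- fixed_config(pos)
  q <- seq(0.2, 3, length.out = 7)
  w <- rep(6, 6)
  expect_equal(debye_intensity(cfg, q), debye_r(pos, w, q), tolerance = 1e-10)
})

test_that("orientational averaging reproduces the Debye sum within 2%", {
  set.seed(12)
  pos <- matrix(runif(45, -0.5, 0.5), ncol = 3)
  cfg <- fixed_config(pos, species = "O")
  q <- seq(0.1, 3, length.out = 15)
  est <- avg_intensity(cfg, q, n_dir = 200, seed = 6)
  oracle <- debye_r(pos, rep(8, 15), q)
  expect_lt(max(abs(est / oracle - 1)), 0.02)
})

test_that("vacuum intensity through the full pipeline matches Debye", {
  set.seed(5)
  pos <- matrix(runif(15, -0.4, 0.4), ncol = 3)
  cfg <- fixed_config(pos, species = "N")
  q <- seq(0.1, 3, length.out = 12)
  cur <- buffer_subtracted_intensity(list(cfg), NULL, NULL, q,
                                     n_directions = 200, "SAXS",
                                     seed = 6, n_blocks = 1)
  oracle <- debye_r(pos, rep(7, 5), q)
  expect_lt(max(abs(cur$I / oracle - 1)), 0.02)
  expect_true(all(cur$sigma == 0))
})

test_that("scaling all form factors by c scales the intensity by c^2", {
  set.seed(3)
  pos <- matrix(runif(12, -0.3, 0.3), ncol = 3)
  q <- seq(0.2, 2, length.out = 5)
  tab <- species_table()
  tab2 <- tab
  tab2$electrons <- tab2$electrons * 3
  c1 <- atomic_configuration(pos, rep("C", 4), rep("solute", 4), box = 40,
                             species_table = tab)
  c2 <- atomic_configuration(pos, rep("C", 4), rep("solute", 4), box = 40,
                             species_table = tab2)
  i1 <- avg_intensity(c1, q, n_dir = 50)
  i2 <- avg_intensity(c2, q, n_dir = 50)
  expect_equal(i2, 9 * i1, tolerance = 1e-9)
})

test_that("density correction factor recovers imposed density offsets", {
  spec <- small_spec()
  env <- build_envelope(make_solute(spec), 0.6, subdivision_level = 3)
  buf <- make_ensemble("buffer", n_frames = 40, seed = 6, spec = spec)
  f <- density_correction_factor(buf, env, "SAXS")
  n_env <- 33.4 * envelope_volume(env) * 40
  pois <- 3 / sqrt(n_env)           # 3 sigma on the measured mean density
  expect_lt(abs(f - 1), pois + 0.01)

  ## buffer generated at 95% of the target -> factor ~ 1/0.95
  spec95 <- small_spec(bulk_electron_density = 0.95 * 334)
  buf95 <- make_ensemble("buffer", n_frames = 40, seed = 6, spec = spec95)
  f95 <- density_correction_factor(buf95, env,
                                   modality_spec("SAXS",
                                                 target_bulk_density = 334))
  expect_lt(abs(f95 - 1 / 0.95), 3.5 / sqrt(0.95 * n_env) + 0.01)
  expect_equal(attr(f95, "target"), 334)
})

test_that("uniform-contrast lattice sphere matches the analytic form factor", {
  spec <- synthetic_spec(solute_atom_spacing = 0.15, box_edge = 5)
  sol <- make_solute(spec)
  q <- seq(0.2, pi, length.out = 12)
  I <- avg_intensity(sol, q, n_dir = 200, seed = 9)
  I0 <- sum(hydrosas:::scattering_weights(sol, "SAXS"))^2
  expect_lt(max(abs(I / I0 / sphere_ff(q, 1.0) - 1)), 0.03)
})

test_that("envelopes larger than the box are rejected", {
  spec <- small_spec()
  sol <- make_solute(spec)
  env <- build_envelope(sol, distance = 2.5, subdivision_level = 2)
  qv <- matrix(c(0.1, 0, 0), 1)
  expect_error(sas_amplitude(solvate(sol, spec), env, qv),
               "beyond the simulation box")
})

test_that("block-count preconditions are enforced", {
  spec <- small_spec()
  sys <- make_ensemble("system", n_frames = 4, seed = 1, spec = spec)
  buf <- make_ensemble("buffer", n_frames = 4, seed = 2, spec = spec)
  env <- build_envelope(sys[[1]], 0.6, subdivision_level = 2)
  expect_error(sas_curves(sys, buf, env, c(0.1, 0.2), 20, "SAXS",
                          n_blocks = 10),
               "fewer frames than blocks")
})
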