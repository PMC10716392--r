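test_that("icosphere subdivision gives 20 * 4^L faces (81920 at level 6)", {
  for (lev in c(2, 4)) {
    ico <- hydrosas:::icosphere(lev)
    expect_equal(nrow(ico$faces), 20 * 4^lev)
    expect_equal(nrow(ico$directions), 2 + 10 * 4^lev)
    expect_equal(rowSums(ico$directions^2), rep(1, nrow(ico$directions)),
                 tolerance = 1e-12)
  }
  expect_equal(nrow(hydrosas:::icosphere(6)$faces), 81920)
})

test_that("single-atom envelope is a sphere of radius distance + vdW", {
  cfg <- fixed_config(c(0, 0, 0), species = "C", box = 20)
  env <- build_envelope(cfg, distance = 0.9, subdivision_level = 5)
  r <- 0.9 + species_table()$vdw_nm[species_table()$label == "C"]
  expect_lt(abs(envelope_volume(env) / (4 / 3 * pi * r^3) - 1), 0.01)
  expect_equal(env$build_distance, 0.9)

  ## the atom itself and the center are inside; far points are not
  expect_true(envelope_inside(env, c(0, 0, 0)))
  expect_false(envelope_inside(env, 10 * max(env$radial_distance) * c(1, 0, 0)))
})

test_that("Monte-Carlo volume via inside() matches the mesh volume", {
  spec <- small_spec()
  env <- build_envelope(make_solute(spec), distance = 0.5,
                        subdivision_level = 4)
  rmax <- max(env$radial_distance)
  set.seed(42)
  pts <- matrix(runif(3 * 2e5, -rmax, rmax), ncol = 3)
  frac <- mean(envelope_inside(env, pts))
  vol_mc <- frac * (2 * rmax)^3
  se <- sqrt(frac * (1 - frac) / 2e5) * (2 * rmax)^3
  expect_lt(abs(vol_mc - envelope_volume(env)), max(3.5 * se,
                                                    0.01 * envelope_volume(env)))
})

test_that("every construction atom's ball lies inside the envelope", {
  spec <- small_spec()
  frames <- make_ensemble("system", n_frames = 2, seed = 3, spec = spec,
                          lazy = FALSE)
  ## jittered solute: envelope must enclose solute atoms of all frames
  frames[[2]]$positions[frames[[2]]$role == "solute", ] <-
    frames[[2]]$positions[frames[[2]]$role == "solute", ] + 0.05
  env <- build_envelope(frames, distance = 0.7, subdivision_level = 4)
  set.seed(7)
  for (fr in frames) {
    sol <- fr$positions[fr$role == "solute", , drop = FALSE]
    vdw <- spec$solute_vdw_radius
    ## random points on the required balls
    k <- sample(nrow(sol), 200, replace = TRUE)
    u <- matrix(rnorm(600), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sol[k, ] + (vdw + 0.7) * u * runif(200)^(1 / 3)
    expect_true(all(envelope_inside(env, pts)))
  }
})

test_that("radial distances grow monotonically with build distance", {
  spec <- small_spec()
  sol <- make_solute(spec)
  e1 <- build_envelope(sol, distance = 0.4, subdivision_level = 3)
  e2 <- build_envelope(sol, distance = 0.8, subdivision_level = 3)
  expect_true(all(e2$radial_distance >= e1$radial_distance))
})

test_that("nested envelopes are strictly nested with analytic shell volumes", {
  cfg <- fixed_config(c(0, 0, 0), species = "C", box = 30)
  vdw <- species_table()$vdw_nm[species_table()$label == "C"]
  envs <- nested_envelopes(cfg, start_distance = 0.1, spacing = 0.1,
                           count = 3, subdivision_level = 5)
  for (k in 1:2) {
    expect_true(all(envs[[k + 1]]$radial_distance > envs[[k]]$radial_distance))
  }
  vols <- vapply(envs, envelope_volume, numeric(1))
  radii <- vdw + c(0.1, 0.2, 0.3)
  analytic <- 4 / 3 * pi * diff(radii^3)
  expect_lt(max(abs(diff(vols) / analytic - 1)), 0.02)
})

test_that("envelope serializes to an OFF mesh and round-trips its vertices", {
  spec <- small_spec()
  env <- build_envelope(make_solute(spec), 0.5, subdivision_level = 2)
  f <- tempfile(fileext = ".off")
  write_envelope_off(env, f)
  lines <- readLines(f)
  expect_identical(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(counts[1:2], c(nrow(env$directions), nrow(env$faces)))
  v1 <- as.numeric(strsplit(lines[3], " ")[[1]])
  expect_equal(v1, env$radial_distance[1] * env$directions[1, ] + env$center,
               tolerance = 1e-6)
})
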