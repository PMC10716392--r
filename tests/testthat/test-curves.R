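test_that("Guinier fit is exact on an exact Guinier curve", {
  rg <- 1.5
  q <- seq(0.05, 1.2, length.out = 30)
  cv <- sas_curve(q, 100 * exp(-q^2 * rg^2 / 3))
  g <- guinier_fit(cv)
  expect_equal(g$Rg, rg, tolerance = 1e-9)
  expect_equal(g$I0, 100, tolerance = 1e-9)
  expect_lte(max(g$q_range_used) * g$Rg, 1.3 + 1e-9)
})

test_that("Guinier on the analytic sphere curve recovers sqrt(3/5) R", {
  R <- 1
  q <- seq(0.05, 3, length.out = 60)
  cv <- sas_curve(q, sphere_ff(q, R))
  ## spheres have strong fourth-order curvature; the conservative range
  ## qmax*Rg <= 0.8 keeps the Guinier approximation itself within ~0.7%
  g <- guinier_fit(cv, qrg_max = 0.8)
  expect_lt(abs(g$Rg / (sqrt(3 / 5) * R) - 1), 0.01)
})

test_that("flat curves give Rg = 0 and all-negative heads are refused", {
  q <- seq(0.05, 1, length.out = 10)
  expect_lt(guinier_fit(sas_curve(q, rep(7, 10)))$Rg, 1e-6)
  expect_error(guinier_fit(sas_curve(q, rep(-1, 10))),
               "non-positive intensities")
})

test_that("P(r) inversion round-trips a uniform-sphere distance histogram", {
  ## P(r) of a uniform sphere of radius R (diameter = Dmax), closed form
  R <- 1
  r <- seq(0, 2 * R, length.out = 201)
  x <- r / (2 * R)
  P_true <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  P_true[r > 2 * R] <- 0
  q <- seq(0.05, 6, length.out = 80)
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  I <- 4 * pi * (r[2] - r[1]) * as.vector(outer(q, r, function(qq, rr)
    sinc(qq * rr)) %*% P_true)
  p <- pddf_invert(sas_curve(q, I), Dmax = 2 * R)
  scale <- max(P_true)
  expect_lt(max(abs(p$P - P_true)) / scale, 0.05)
  expect_equal(p$P[1], 0)
  expect_equal(p$P[length(p$P)], 0)
  ## Rg from the recovered P(r) matches the sphere value
  expect_lt(abs(rg_from_pddf(p) / (sqrt(3 / 5) * R) - 1), 0.01)
})

test_that("stronger regularization never increases roughness", {
  R <- 1
  q <- seq(0.05, 5, length.out = 50)
  cv <- sas_curve(q, sphere_ff(q, R))
  rough <- function(p) {
    d2 <- diff(diff(p$P))
    sum(d2^2)
  }
  lams <- 10^seq(-6, 2, by = 2)
  vals <- vapply(lams, function(l) rough(pddf_invert(cv, 2, lambda = l)),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-9 * max(vals)))
})

test_that("zero curves invert to P = 0 and Rg is then undefined", {
  q <- seq(0.05, 3, length.out = 30)
  p <- pddf_invert(sas_curve(q, rep(0, 30)), Dmax = 2)
  expect_equal(max(abs(p$P)), 0, tolerance = 1e-12)
  expect_error(rg_from_pddf(p), "zero")
})

test_that("rg_from_pddf handles closed forms: sphere and two-point spike", {
  R <- 1.3
  r <- seq(0, 2 * R, length.out = 401)
  x <- r / (2 * R)
  P <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  expect_lt(abs(pddf_rg_wrap(r, P) / (sqrt(3 / 5) * R) - 1), 1e-3)

  ## two equal point scatterers at distance d: the distance histogram has
  ## equal mass in the self-term at r = 0 and the cross-term at r = d,
  ## and the brute-force two-point Rg is d/2
  d <- 0.8
  rs <- seq(0, 1.6, length.out = 1601)
  sig <- 0.004
  Ps <- exp(-(rs - d)^2 / (2 * sig^2)) + 2 * exp(-rs^2 / (2 * sig^2))
  expect_lt(abs(pddf_rg_wrap(rs, Ps) - d / 2), 2e-3)
})

test_that("Guinier and P(r) routes agree on noise-free compact bodies", {
  for (R in c(0.8, 1.5)) {
    q <- seq(0.05, 6 / R, length.out = 80)
    cv <- sas_curve(q, 50 * sphere_ff(q, R))
    g <- guinier_fit(cv, qrg_max = 0.8)
    p <- pddf_invert(cv, Dmax = 2 * R)
    expect_lt(abs(g$Rg - rg_from_pddf(p)) / g$Rg, 0.01)
  }
})

test_that("direct-space Rg: trivial cases, weighting, and equivariance", {
  one <- fixed_config(c(1, 2, 3))
  expect_equal(rg_direct(one, "uniform"), 0)
  two <- fixed_config(rbind(c(0, 0, 0), c(0, 0, 0.8)))
  expect_equal(rg_direct(two, "uniform"), 0.4)
  ## translation invariance and scale equivariance on a random cloud
  set.seed(31)
  pos <- matrix(runif(30, -1, 1), ncol = 3)
  a <- rg_direct(fixed_config(pos), "contrast_electrons")
  b <- rg_direct(fixed_config(sweep(pos, 2, c(3, -2, 1), `+`)),
                 "contrast_electrons")
  expect_equal(a, b, tolerance = 1e-9)
  expect_equal(rg_direct(fixed_config(2 * pos), "contrast_electrons"), 2 * a,
               tolerance = 1e-9)
  ## nsl weighting differs from electron weighting for mixed species
  mix <- atomic_configuration(pos, rep(c("C", "O", "H"), 10)[1:10],
                              rep("solute", 10), box = 40)
  expect_false(isTRUE(all.equal(rg_direct(mix, "contrast_nsl"),
                                rg_direct(mix, "contrast_electrons"))))
  expect_error(rg_direct(one, atom_subset = logical(1)), "empty")
})
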