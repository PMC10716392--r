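test_that("block statistics reproduce definitional cases", {
  ## constant statistic -> SE = 0
  bs <- block_statistics(rep(5, 40), n_blocks = 10, statistic = mean)
  expect_equal(unname(bs$mean), 5)
  expect_equal(unname(bs$se), 0)
  ## per-block values exposed for pairing; SE = sd/sqrt(n_blocks) exactly
  set.seed(2)
  x <- rnorm(100)
  bs2 <- block_statistics(x, n_blocks = 10, statistic = mean)
  expect_equal(unname(bs2$se), sd(bs2$values[1, ]) / sqrt(10))
  expect_equal(unname(bs2$mean), mean(bs2$values[1, ]))
  expect_error(block_statistics(x, n_blocks = 1, statistic = mean),
               "at least 2")
  expect_error(block_statistics(1:5, n_blocks = 10, statistic = mean),
               "fewer frames")
  ## paired buffer blocks are passed through positionally
  got <- block_statistics(1:20, n_blocks = 10, buffer = 101:120,
                          statistic = function(a, b) mean(b) - mean(a))
  expect_equal(unname(got$mean), 100)
  expect_equal(unname(got$se), 0)
})

test_that("delta-Rg report holds its arithmetic identities", {
  res <- list(SAXS = list(Rg = 1.62, se = 0.01),
              SANS_H2O = list(Rg = 1.60, se = 0.02),
              SANS_D2O = list(Rg = 1.55, se = 0.03))
  rep_ <- delta_rg_report(res, rg_prot = 1.59)
  expect_equal(unname(rep_$dRg["SAXS"]), 1.62 - 1.59)
  expect_equal(unname(rep_$dRg_SAS["SANS_D2O"]), 1.62 - 1.55)
  expect_equal(unname(rep_$dRg_SAS["SANS_H2O"]), 1.62 - 1.60)
  expect_equal(unname(rep_$dRg_SAS_se["SANS_D2O"]), sqrt(0.01^2 + 0.03^2))
  expect_true(all(rep_$dRg_se >= 0))
  ## Rg(SAXS) = Rg(prot) -> dRg(SAXS) = 0
  rep0 <- delta_rg_report(list(SAXS = list(Rg = 1.59, se = 0)), rg_prot = 1.59)
  expect_equal(unname(rep0$dRg["SAXS"]), 0)
  ## block-paired SE absorbs correlation
  bl <- list(SAXS = list(Rg = 1.62, se = 0.01, blocks = 1.62 + (1:10) / 100),
             SANS_D2O = list(Rg = 1.55, se = 0.03, blocks = 1.55 + (1:10) / 100))
  repb <- delta_rg_report(bl, rg_prot = 1.59)
  expect_equal(unname(repb$dRg_SAS_se["SANS_D2O"]), 0)   # perfectly correlated
})

test_that("consensus averaging combines members as documented", {
  one <- consensus_average(list(c(2.5, 0.1)))
  expect_equal(one$mean, 2.5)
  expect_equal(one$se, 0.1)
  six <- consensus_average(lapply(1:6, function(i) c(1.7, 0.2)))
  expect_equal(six$mean, 1.7)
  expect_equal(six$se, 0)                      # no between-member scatter
  expect_error(consensus_average(list()), "empty")
  ## six members drawn from a known Gaussian: mean within 3 SE of truth
  set.seed(13)
  draws <- lapply(1:6, function(i) c(rnorm(1, 3, 0.5), 0.1))
  ca <- consensus_average(draws)
  expect_lt(abs(ca$mean - 3), 3 * max(ca$se, 0.5 / sqrt(6)))
})

test_that("density profiles recover the shell excess and bulk far field", {
  spec <- synthetic_spec()
  n_frames <- 30
  ens <- make_ensemble("system", n_frames = n_frames, seed = 21, spec = spec)
  prof <- density_profile(ens, spacing = 0.1, n_shells = 8,
                          subdivision_level = 3)
  shell_bins <- prof$R < spec$shell_thickness
  far_bins <- prof$R > spec$shell_thickness + 0.2
  expect_true(any(shell_bins) && any(far_bins))
  ## shell bins elevated by ~6%, far bins at 334, each within ~3 Poisson SE
  for (i in which(shell_bins)) {
    expect_lt(abs(prof$density[i] / 334 - 1 - spec$shell_excess),
              3 * prof$se[i] / 334 + 0.015)
  }
  far <- mean(prof$density[far_bins])
  far_se <- sqrt(sum(prof$se[far_bins]^2)) / sum(far_bins)
  expect_lt(abs(far - 334), 3 * far_se + 3)

  ## mass balance: sum(bin density x bin volume) = mean counted content
  vols <- attr(prof, "shell_volumes")
  expect_equal(sum(prof$density * vols), sum(attr(prof, "mean_content")),
               tolerance = 1e-9)
})

test_that("relative profiles subtract pointwise and flag grid mismatch", {
  spec <- small_spec()
  ens <- make_ensemble("system", n_frames = 5, seed = 3, spec = spec)
  prof <- density_profile(ens, spacing = 0.1, n_shells = 5,
                          subdivision_level = 2)
  self <- relative_profile(prof, prof)
  expect_equal(max(abs(self$density)), 0)
  short <- density_profile(ens, spacing = 0.1, n_shells = 2,
                           subdivision_level = 2)
  expect_error(relative_profile(prof, short), "resampling tolerance")
})

test_that("bulk-water reference shows smaller modulations than the shell", {
  spec <- synthetic_spec()
  n_frames <- 15
  sysf <- make_ensemble("system", n_frames = n_frames, seed = 31, spec = spec)
  prof <- density_profile(sysf, spacing = 0.1, n_shells = 6,
                          subdivision_level = 3)
  ref_ens <- make_ensemble("bulk_reference", n_frames = n_frames, seed = 32,
                           spec = spec)
  ref <- density_profile(ref_ens, spacing = 0.1, n_shells = 6,
                         subdivision_level = 3)
  expect_lt(max(abs(ref$density - 334)), max(abs(prof$density - 334)))
  ## and the excess is confined to the shell region
  rel <- relative_profile(prof, ref)
  expect_gt(mean(rel$density[rel$R < spec$shell_thickness]), 0)
})
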