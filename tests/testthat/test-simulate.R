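test_that("forward projection is linear and annihilates zero activity", {
  sys <- small_sys(0)
  ph <- small_phantom()
  zero <- voxel_grid(array(0, dim(ph$labels$values)), c(2, 2, 2),
                     ph$labels$affine)
  expect_true(all(forward_project(zero, sys)$values == 0))
  set.seed(8)
  a <- voxel_grid(array(runif(32^3), c(32, 32, 32)), c(2, 2, 2))
  b <- voxel_grid(array(runif(32^3), c(32, 32, 32)), c(2, 2, 2))
  ab <- voxel_grid(a$values + b$values, c(2, 2, 2))
  lhs <- forward_project(ab, sys)$values
  rhs <- forward_project(a, sys)$values + forward_project(b, sys)$values
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("central ray through a uniform sphere integrates to its diameter", {
  # unit-activity sphere of radius 30 mm: central chord = 60 mm
  n <- 48
  g <- voxel_grid(array(0, c(n, n, 4)), c(2, 2, 2))
  w <- grid_world_coords(g)
  r2 <- w[, 1]^2 + w[, 2]^2
  g$values[] <- as.numeric(r2 <= 30^2)
  sys <- default_system(g, psf_fwhm_mm = 0)
  sino <- forward_project(g, sys)
  rpos <- (seq_len(sys$n_radial) - (sys$n_radial + 1) / 2) * sys$voxel_xy_mm
  central <- which.min(abs(rpos))
  chord <- 2 * sqrt(30^2 - rpos[central]^2)
  got <- sino$values[central, 1, 2]
  expect_equal(got, chord, tolerance = 0.02 * chord)
})

test_that("attenuation factors follow the exponential line-integral law", {
  # mu = 0 everywhere -> all factors 1
  g0 <- voxel_grid(array(0, c(16, 16, 2)), c(2, 2, 2))
  sys0 <- default_system(g0, psf_fwhm_mm = 0)
  expect_true(all(attenuation_factors(g0, sys0)$values == 1))
  # water cylinder, 200 mm diameter: central ray exp(-0.0096 * 200) ~ 0.1466
  n <- 112
  g <- voxel_grid(array(0, c(n, n, 2)), c(2, 2, 2))
  w <- grid_world_coords(g)
  r2 <- w[, 1]^2 + w[, 2]^2
  g$values[] <- 0.0096 * (r2 <= 100^2)
  sys <- default_system(g, psf_fwhm_mm = 0)
  af <- attenuation_factors(g, sys)
  rpos <- (seq_len(sys$n_radial) - (sys$n_radial + 1) / 2) * sys$voxel_xy_mm
  central <- which.min(abs(rpos))
  expected <- exp(-0.0096 * 2 * sqrt(100^2 - rpos[central]^2))
  expect_equal(af$values[central, 1, 1], expected, tolerance = 0.02 * expected)
  # scaling mu up can only decrease the factors
  g2 <- g; g2$values <- g$values * 1.7
  expect_true(all(attenuation_factors(g2, sys)$values <= af$values + 1e-12))
})

test_that("forward and back projection form an adjoint pair", {
  sys <- small_sys(0)
  set.seed(12)
  x <- voxel_grid(array(runif(32^3), c(32, 32, 32)), c(2, 2, 2))
  fx <- forward_project(x, sys)
  y <- fx
  y$values <- array(runif(length(fx$values)), dim(fx$values))
  aty <- back_project(y, sys, x)
  expect_equal(sum(fx$values * y$values), sum(x$values * aty$values),
               tolerance = 1e-6 * sum(fx$values * y$values))
  # and with an image-space PSF (still matched because smoothing is
  # self-adjoint)
  sysp <- small_sys(4)
  fxp <- forward_project(x, sysp)
  atyp <- back_project(y, sysp, x)
  expect_equal(sum(fxp$values * y$values), sum(x$values * atyp$values),
               tolerance = 1e-6 * sum(fxp$values * y$values))
})

test_that("simulated prompts have the configured composition and are seeded", {
  ph <- small_phantom()
  sys <- small_sys(0)
  act <- small_activity()
  sim <- simulate_prompts(act, ph$mu_map, sys, 0.2, 0.1, seed = 5)
  sim2 <- simulate_prompts(act, ph$mu_map, sys, 0.2, 0.1, seed = 5)
  expect_identical(sim$listmode$events, sim2$listmode$events)
  # scatter/randoms expectation fractions
  trues_tot <- sum(forward_project(act, sys)$values *
                     attenuation_factors(ph$mu_map, sys)$values)
  ptot <- trues_tot / 0.7
  expect_equal(sum(sim$scatter$values), 0.2 * ptot, tolerance = 1e-9)
  expect_equal(sum(sim$randoms$values), 0.1 * ptot, tolerance = 1e-9)
  # with no background the expectation equals the attenuated trues
  sim0 <- simulate_prompts(act, ph$mu_map, sys, 0, 0, seed = 5)
  expect_equal(sim0$listmode$n_events, trues_tot,
               tolerance = 4 * sqrt(trues_tot))
})

test_that("total simulated events are Poisson-consistent across seeds", {
  # small system so 100 seeds stay cheap
  g <- voxel_grid(array(0.5, c(12, 12, 2)), c(2, 2, 2))
  mu <- voxel_grid(array(0, c(12, 12, 2)), c(2, 2, 2))
  sys <- default_system(g, psf_fwhm_mm = 0)
  lam <- sum(forward_project(g, sys)$values)
  tot <- vapply(1:100, function(s) {
    simulate_prompts(g, mu, sys, 0, 0, seed = s)$listmode$n_events
  }, 1)
  se <- sqrt(lam / 100)
  expect_lt(abs(mean(tot) - lam), 3 * se)
})

test_that("binning and expanding list-mode data preserves counts exactly", {
  sim <- small_simulation()
  sino <- bin_events(sim$listmode)
  expect_equal(sum(sino$values), sim$listmode$n_events)
  lm2 <- sinogram_to_listmode(sino, seed = 3)
  expect_equal(lm2$n_events, sim$listmode$n_events)
  expect_equal(bin_events(lm2)$values, sino$values)
})

test_that("bootstrap draws the requested number of events with replacement", {
  sim <- small_simulation()
  lm <- sim$listmode
  b1 <- bootstrap_listmode(lm, 1.0, seed = 1)
  expect_equal(b1$n_events, lm$n_events)
  # a full-level resample is still a bootstrap replicate, not a copy
  expect_false(identical(bin_events(b1)$values, bin_events(lm)$values))
  b3 <- bootstrap_listmode(lm, 0.30, seed = 1)
  expect_equal(b3$n_events, round(0.3 * lm$n_events))
  expect_equal(b3$count_level, 0.30)
  empty <- listmode(matrix(integer(0), 0, 3), lm$dims)
  expect_error(bootstrap_listmode(empty, 0.5), "empty")
})

test_that("bootstrap per-bin means are calibrated to the count level", {
  # binomial thinning theory: mean over resamples at level f of each bin
  # approaches f * original count
  sim <- small_simulation()
  lm <- sim$listmode
  orig <- bin_events(lm)$values
  # a capped bin subset keeps the joint 3.5-sigma check meaningful (the
  # per-bin chance failure rate times the bin count stays well below one)
  hot <- utils::head(which(orig >= 20), 150)
  acc <- matrix(0, length(hot), 50)
  for (r in 1:50) {
    b <- bootstrap_listmode(lm, 0.3, seed = 1000 + r)
    acc[, r] <- bin_events(b)$values[hot]
  }
  m <- rowMeans(acc)
  se <- sqrt(0.3 * orig[hot] / 50)
  expect_true(all(abs(m - 0.3 * orig[hot]) <= 3.5 * se))
})

test_that("list-mode TSV round-trip preserves the stream", {
  sim <- small_simulation()
  lm <- bootstrap_listmode(sim$listmode, 0.01, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_listmode(lm, path)
  back <- read_listmode(path)
  expect_equal(back$events, lm$events)
  expect_equal(back$count_level, lm$count_level)
  expect_equal(back$dims, lm$dims)
  unlink(c(path, paste0(path, ".json")))
})
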