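# independent single-subset MLEM oracle built from the public projector API
mlem_oracle <- function(prompts, sys, grid, n_iter, af = NULL) {
  d <- dim(grid$values)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  fov <- outer(seq_len(d[1]), seq_len(d[2]),
               function(i, j) (i - cx)^2 + (j - cy)^2 <= (min(d[1], d[2]) / 2)^2)
  x <- voxel_grid(array(rep(as.numeric(fov), d[3]), d), grid$voxel_size_mm,
                  grid$affine)
  one <- prompts; one$values <- array(1, dim(prompts$values))
  if (!is.null(af)) one$values <- af$values
  sens <- back_project(one, sys, grid)
  for (it in seq_len(n_iter)) {
    fp <- forward_project(x, sys)
    if (!is.null(af)) fp$values <- fp$values * af$values
    ratio <- prompts
    ratio$values <- ifelse(fp$values > 0, prompts$values / fp$values, 0)
    if (!is.null(af)) ratio$values <- ratio$values * af$values
    bp <- back_project(ratio, sys, grid)
    x$values <- x$values * ifelse(sens$values > 0, bp$values / sens$values, 0)
  }
  x
}

test_that("all-zero prompts give an all-zero image after one update", {
  p <- tiny_recon_problem()
  zp <- p$prompts; zp$values[] <- 0
  img <- osem(zp, p$sys, recon_config("NAC", 1, 1), p$truth)
  expect_true(all(img$values == 0))
})

test_that("single-subset OSEM matches an independent MLEM oracle bitwise", {
  p <- tiny_recon_problem()
  got <- osem(p$prompts, p$sys, recon_config("NAC", 5, 1), p$truth)
  want <- mlem_oracle(p$prompts, p$sys, p$truth, 5)
  expect_identical(got$values, want$values)
})

test_that("MLEM log-likelihood is non-decreasing over ten iterations", {
  p <- tiny_recon_problem()
  img <- osem(p$prompts, p$sys, recon_config("NAC", 10, 1), p$truth,
              track_loglik = TRUE)
  ll <- attr(img, "loglik")
  expect_length(ll, 10)
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-1])))
})

test_that("MLEM preserves sensitivity-weighted image mass", {
  p <- tiny_recon_problem()
  one <- p$prompts; one$values[] <- 1
  sens <- back_project(one, p$sys, p$truth)
  for (iters in c(1, 3)) {
    img <- osem(p$prompts, p$sys, recon_config("NAC", iters, 1), p$truth)
    expect_equal(sum(img$values * sens$values), sum(p$prompts$values),
                 tolerance = 1e-6)
  }
})

test_that("noiseless AC reconstruction recovers the grey-matter mean within 3%", {
  ph <- small_phantom()
  sys <- small_sys(0)
  act <- small_activity()
  af <- attenuation_factors(ph$mu_map, sys)
  noiseless <- forward_project(act, sys)
  noiseless$values <- noiseless$values * af$values
  prompts <- sinogram(noiseless$values, kind = "prompts")
  img <- osem(prompts, sys, recon_config("AC", 20, 14), ph$labels, af = af)
  gm <- ph$labels$values %in% ph$regions$label_id[ph$regions$tissue == "GM"]
  expect_equal(mean(img$values[gm]), mean(act$values[gm]),
               tolerance = 0.03)
})

test_that("reconstruction modes enforce their correction inputs", {
  p <- tiny_recon_problem()
  expect_error(osem(p$prompts, p$sys, recon_config("AC", 1, 1), p$truth),
               "attenuation")
  neg <- p$prompts; neg$values[1] <- -1
  expect_error(sinogram(neg$values, kind = "randoms"))
})

test_that("more OSEM iterations give noisier images across bootstrap replicates", {
  ph <- small_phantom()
  sys <- small_sys(0)
  sim <- small_simulation()
  gm <- ph$labels$values %in% ph$regions$label_id[ph$regions$tissue == "GM"]
  vox_sd <- sapply(c(1L, 2L, 3L), function(iters) {
    imgs <- sapply(1:8, function(r) {
      lm <- bootstrap_listmode(sim$listmode, 0.3, seed = 400 + r)
      img <- osem(bin_events(lm), sys, recon_config("AC", iters, 14),
                  ph$labels, af = sim$af,
                  randoms_est = sinogram(sim$randoms$values * 0.3,
                                         kind = "randoms"))
      img$values[gm]
    })
    mean(apply(imgs, 1, sd))
  })
  expect_true(all(diff(vox_sd) > 0))
})

test_that("scatter estimation is conservative, linear and non-negative", {
  ph <- small_phantom()
  sys <- small_sys(0)
  act <- small_activity()
  af <- attenuation_factors(ph$mu_map, sys)
  # scatter-free, randoms-free simulation: the tail fit should find ~nothing
  sim0 <- simulate_prompts(act, ph$mu_map, sys, 0, 0, seed = 21)
  p0 <- bin_events(sim0$listmode)
  s0 <- estimate_scatter(p0, af)
  expect_true(all(s0$values >= 0))
  expect_lte(sum(s0$values), 0.05 * sum(p0$values))
  # doubling the prompts doubles the estimate
  p2 <- sinogram(p0$values * 2, kind = "prompts")
  s2 <- estimate_scatter(p2, af)
  expect_equal(s2$values, 2 * s0$values, tolerance = 1e-9)
  # with real scatter present the estimate recovers a sizeable share of it
  simS <- small_simulation()
  pS <- bin_events(simS$listmode)
  rS <- sinogram(simS$randoms$values, kind = "randoms")
  sS <- estimate_scatter(pS, af, rS)
  expect_gt(sum(sS$values), 0.3 * sum(simS$scatter$values))
  expect_lte(sum(sS$values), sum(pS$values))
})
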