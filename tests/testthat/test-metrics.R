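test_that("Dice and Jaccard reproduce the worked overlap cases", {
  a <- c(rep(TRUE, 4), rep(FALSE, 6))
  b <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # |A| = 4, |B| = 6, |A n B| = 3
  expect_identical(dice(a, b), 0.6)
  expect_equal(jaccard(a, b), 3 / 7, tolerance = 1e-15)
  # identity and disjoint
  expect_identical(dice(a, a), 1)
  expect_identical(jaccard(b, b), 1)
  expect_identical(dice(a, !a), 0)
  expect_identical(jaccard(a, !a), 0)
  # symmetry
  expect_identical(dice(a, b), dice(b, a))
  expect_error(dice(logical(5), logical(5)), "empty")
})

test_that("dice-jaccard functional identity holds on random mask pairs", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(20:400, 1)
    a <- runif(n) < runif(1, 0.2, 0.8)
    b <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(a) && !any(b)) next
    # brute-force set arithmetic oracle
    ii <- sum(a & b); uu <- sum(a | b)
    j_expect <- ii / uu
    d_expect <- 2 * ii / (sum(a) + sum(b))
    expect_equal(jaccard(a, b), j_expect, tolerance = 1e-15)
    expect_equal(dice(a, b), d_expect, tolerance = 1e-15)
    j <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("SUVr is a ratio of regional means, scale-invariant", {
  vals <- array(1, c(6, 6, 2))
  lab <- array(0L, c(6, 6, 2))
  lab[1:3, , 1] <- 1L   # target
  lab[4:6, , 1] <- 2L   # reference
  pet <- voxel_grid(vals, c(2, 2, 2))
  labs <- voxel_grid(lab, c(2, 2, 2))
  expect_equal(suvr(pet, labs, 1, 2)$suvr, 1)
  pet$values[lab == 1L] <- 2.4
  pet$values[lab == 2L] <- 1.2
  expect_equal(suvr(pet, labs, 1, 2)$suvr, 2)
  pet7 <- pet; pet7$values <- pet$values * 7
  expect_equal(suvr(pet7, labs, 1, 2)$suvr, suvr(pet, labs, 1, 2)$suvr,
               tolerance = 1e-12)
  expect_error(suvr(pet, labs, 3, 2), "empty")
})

test_that("coefficient of variation matches its closed form", {
  expect_identical(coeff_var(c(1, 1, 1, 1)), 0)
  expect_equal(coeff_var(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
  set.seed(1); x <- rlnorm(50)
  expect_equal(coeff_var(3 * x), coeff_var(x), tolerance = 1e-12)
  expect_error(coeff_var(c(-1, 1)), "zero mean")
})

test_that("Brown-Forsythe behaves like its definition", {
  x <- c(1.2, 3.4, 2.2, 5.0, 0.7, 2.9)
  out <- brown_forsythe(list(x, x))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  # shift invariance: median-centred deviations ignore location
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20, sd = 2)
  s1 <- brown_forsythe(list(a, b))$statistic
  s2 <- brown_forsythe(list(a + 100, b))$statistic
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("Brown-Forsythe agrees with the median-centred Levene reference and a permutation null", {
  set.seed(101)
  a <- rnorm(50, sd = 1)
  b <- rnorm(50, sd = 3)
  got <- brown_forsythe(list(a, b))
  expect_lt(got$p_value, 0.01)
  # cross-check statistic and p against car's median-centred Levene test
  df <- data.frame(y = c(a, b), g = factor(rep(1:2, each = 50)))
  ref <- car::leveneTest(y ~ g, data = df, center = median)
  expect_equal(got$statistic, ref[1, "F value"], tolerance = 1e-9)
  expect_equal(got$p_value, ref[1, "Pr(>F)"], tolerance = 1e-9)
  # permutation-null oracle: p estimated by shuffling group labels
  pool <- c(a, b)
  stat_obs <- got$statistic
  perm <- vapply(1:400, function(i) {
    idx <- sample(100, 50)
    brown_forsythe(list(pool[idx], pool[-idx]))$statistic
  }, 1)
  p_perm <- mean(perm >= stat_obs)
  expect_lt(p_perm, 0.01)
})

test_that("a zero-spread group is valid Brown-Forsythe input", {
  out <- brown_forsythe(list(c(1, 1, 1), c(0, 2, 4)))
  expect_true(is.finite(out$statistic) || is.infinite(out$statistic))
  expect_gte(out$statistic, 0)
})

test_that("iterative-Yang PVC restores piecewise-constant regional means", {
  # two slabs (values 4 and 1, 20 voxels wide) blurred with FWHM 3 voxels
  d <- c(60, 16, 16)
  lab <- array(0L, d)
  lab[11:30, 4:13, 4:13] <- 1L
  lab[31:50, 4:13, 4:13] <- 2L
  truth <- array(0, d)
  truth[lab == 1L] <- 4
  truth[lab == 2L] <- 1
  fwhm_vox <- 3
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  blurred <- gauss_smooth3(truth, rep(sigma, 3))
  pet <- voxel_grid(blurred, c(1, 1, 1))
  labs <- voxel_grid(lab, c(1, 1, 1))
  # before correction the hot region is underestimated
  expect_lt(mean(blurred[lab == 1L]), 4)
  out <- yang_pvc(pet, labs, psf_fwhm_mm = fwhm_vox, n_iter = 5, rel_tol = 0)
  m1 <- mean(out$values[lab == 1L])
  m2 <- mean(out$values[lab == 2L])
  expect_equal(m1, 4, tolerance = 0.02 * 4)
  expect_equal(m2, 1, tolerance = 0.02 * 1)
})

test_that("Yang PVC error is non-increasing over the first iterations", {
  d <- c(40, 12, 12)
  lab <- array(0L, d)
  lab[6:20, 3:10, 3:10] <- 1L
  lab[21:35, 3:10, 3:10] <- 2L
  truth <- array(0, d); truth[lab == 1L] <- 3; truth[lab == 2L] <- 1
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  pet <- voxel_grid(gauss_smooth3(truth, rep(sigma, 3)), c(1, 1, 1))
  labs <- voxel_grid(lab, c(1, 1, 1))
  errs <- vapply(1:5, function(k) {
    out <- yang_pvc(pet, labs, psf_fwhm_mm = 2, n_iter = k, rel_tol = 0)
    abs(mean(out$values[lab == 1L]) - 3) + abs(mean(out$values[lab == 2L]) - 1)
  }, 1)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("degenerate PVC inputs pass through unchanged", {
  ph <- small_phantom()
  pet <- voxel_grid(array(runif(32^3), c(32, 32, 32)), c(2, 2, 2))
  # zero-width PSF: bitwise identity
  out0 <- yang_pvc(pet, ph$labels, psf_fwhm_mm = 0)
  expect_identical(out0$values, pet$values)
  # uniform image with full-coverage labels: unchanged away from edges
  u <- voxel_grid(array(1, c(32, 32, 32)), c(2, 2, 2))
  full <- voxel_grid(array(1L, c(32, 32, 32)), c(2, 2, 2))
  outu <- yang_pvc(u, full, psf_fwhm_mm = 6)
  core <- outu$values[10:22, 10:22, 10:22]
  expect_lt(max(abs(core - 1)), 1e-9)
})

test_that("sd_matrix summarises Dice distributions and flags minima", {
  set.seed(3)
  base <- tidyr::expand_grid(
    frame = "late_neg", mode = "AC", iterations = 1:2,
    count_level = 0.3, engine = "nmi", replicate = 1:10,
    roi = c("A", "B")
  )
  base$dice <- ifelse(base$iterations == 1, 0.9 + rnorm(nrow(base), 0, 0.001),
                      0.9 + rnorm(nrow(base), 0, 0.05))
  base$dice <- pmin(pmax(base$dice, 0), 1)
  base$converged <- TRUE
  um <- sd_matrix(base)
  av <- um$average
  expect_equal(nrow(av), 2)
  expect_true(av$is_min[av$iterations == 1])
  # ROI-average equals the unweighted mean of per-ROI SDs
  pr <- tidy(um)
  for (i in seq_len(nrow(av))) {
    sds <- pr$sd[pr$iterations == av$iterations[i]]
    expect_equal(av$sd_mean[i], mean(sds), tolerance = 1e-12)
  }
  # flags stable under row reordering
  um2 <- sd_matrix(base[sample(nrow(base)), ])
  expect_equal(dplyr::arrange(um2$average, iterations)$is_min,
               dplyr::arrange(av, iterations)$is_min)
  # failed registrations are excluded and counted
  base$converged[1:2] <- FALSE
  um3 <- sd_matrix(base)
  expect_equal(sum(um3$per_roi$n_failed), 2L)
  # identical samples in a cell give SD 0 and the min flag
  const <- base
  const$dice <- ifelse(const$iterations == 1, 0.8, const$dice)
  const$converged <- TRUE
  um4 <- sd_matrix(const)
  expect_equal(um4$average$sd_mean[um4$average$iterations == 1], 0)
  expect_true(um4$average$is_min[um4$average$iterations == 1])
})

test_that("tidiers and autoplot provide the standard summaries", {
  base <- tidyr::expand_grid(
    frame = "f", mode = "AC", iterations = 1:2, count_level = c(0.05, 0.6),
    engine = "nmi", replicate = 1:5, roi = "A"
  )
  set.seed(1)
  base$dice <- runif(nrow(base), 0.7, 1)
  base$converged <- TRUE
  um <- sd_matrix(base)
  expect_s3_class(tidy(um), "tbl_df")
  gl <- glance(um)
  expect_equal(gl$n_cells, 4L)
  p <- ggplot2::autoplot(um)
  expect_s3_class(p, "ggplot")
  rr <- registration_result(rigid_transform(c(1, 2, 3), c(4, 5, 6)),
                            1.4, TRUE, 100L)
  td <- tidy(rr)
  expect_equal(td$value, c(1, 2, 3, 4, 5, 6))
  expect_true(glance(rr)$converged)
})
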