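#' Reconstruction configuration
#'
#' @param mode `"NAC"` (no attenuation correction, scatter also omitted),
#'   `"AC"` (attenuation corrected), or `"QNT"` (fully quantitative:
#'   attenuation + scatter). Randoms are corrected in all modes.
#' @param iterations number of OSEM iterations (>= 1; the study grid is
#'   1-3).
#' @param subsets number of angle-interleaved subsets (default 14; must
#'   divide the system's angle count).
#' @param out_voxel_mm output voxel size: 2.0 reconstructs natively, 1.0
#'   additionally applies [upsample_split()] (interpolation-free).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(mode = c("AC", "NAC", "QNT"), iterations = 2L,
                         subsets = 14L, out_voxel_mm = 2.0) {
  mode <- match.arg(toupper(mode[1]), c("AC", "NAC", "QNT"))
  stopifnot(iterations >= 1, subsets >= 1, out_voxel_mm %in% c(2.0, 1.0))
  structure(
    list(mode = mode, iterations = as.integer(iterations),
         subsets = as.integer(subsets), out_voxel_mm = out_voxel_mm),
    class = "recon_config"
  )
}

subset_rows <- function(sys, subsets) {
  stopifnot(sys$n_angles %% subsets == 0)
  lapply(seq_len(subsets), function(k) {
    angles <- seq(k, sys$n_angles, by = subsets)
    as.vector(outer(seq_len(sys$n_radial), (angles - 1L) * sys$n_radial, "+"))
  })
}

#' Poisson log-likelihood of a sinogram under a mean model
#'
#' `sum(m * log(ybar) - ybar)` over bins with positive expected counts
#' (constant `log(m!)` terms dropped).
#'
#' @param m measured counts (array or [sinogram()]).
#' @param ybar expected counts (array or [sinogram()]).
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(m, ybar) {
  if (inherits(m, "sinogram")) m <- m$values
  if (inherits(ybar, "sinogram")) ybar <- ybar$values
  ok <- ybar > 0
  sum(m[ok] * log(ybar[ok]) - ybar[ok]) - sum(ybar[!ok])
}

#' OSEM reconstruction
#'
#' Ordered-subsets expectation maximization with the multiplicative update
#' over angle-interleaved subsets. The data model is
#' `ybar = af * A x + s + r`; correction sinograms enter the denominator of
#' the update ratio, never by pre-correcting the data. The initial image is
#' uniform 1 inside the inscribed field-of-view cylinder. The result is
#' bit-reproducible given fixed inputs.
#'
#' @param prompts measured [sinogram()] of kind `"prompts"`.
#' @param sys the [system_model()] used for reconstruction (typically
#'   without PSF: no resolution modelling).
#' @param cfg a [recon_config()].
#' @param grid [voxel_grid()] giving the output geometry (values ignored).
#' @param af attenuation-factor [sinogram()] (required for AC/QNT).
#' @param scatter_est,randoms_est additive-term [sinogram()]s or `NULL`.
#' @param track_loglik when `TRUE`, attach the per-full-iteration Poisson
#'   log-likelihood as attribute `"loglik"`.
#' @return reconstructed [voxel_grid()], non-negative.
#' @export
osem <- function(prompts, sys, cfg, grid, af = NULL, scatter_est = NULL,
                 randoms_est = NULL, track_loglik = FALSE) {
  check_sys_grid(grid, sys)
  d <- dim(grid$values)
  rows <- subset_rows(sys, cfg$subsets)
  npix <- d[1] * d[2]
  pr <- projection_matrix(d[1], d[2], sys$voxel_xy_mm, sys$n_angles,
                          sys$n_radial)
  m <- matrix(prompts$values, sys$n_radial * sys$n_angles, d[3])

  use_af <- cfg$mode %in% c("AC", "QNT")
  use_sc <- cfg$mode == "QNT"
  if (use_af && is.null(af)) stop(cfg$mode, " reconstruction requires attenuation factors")
  afm <- if (use_af) matrix(af$values, nrow(m), d[3]) else matrix(1, 1, 1)
  addm <- matrix(0, nrow(m), d[3])
  if (!is.null(randoms_est)) {
    if (min(randoms_est$values) < 0) stop("negative randoms estimate")
    addm <- addm + matrix(randoms_est$values, nrow(m), d[3])
  }
  if (use_sc && !is.null(scatter_est)) {
    if (min(scatter_est$values) < 0) stop("negative scatter estimate")
    addm <- addm + matrix(scatter_est$values, nrow(m), d[3])
  }

  psf <- sys$psf_fwhm_mm > 0
  sig <- if (psf) psf_sigma_vox(grid, sys) else NULL
  smooth_img <- function(X) {
    a <- gauss_smooth3(array(X, d), sig)
    matrix(a, npix, d[3])
  }

  # FOV mask: inscribed cylinder
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rad2 <- (min(d[1], d[2]) / 2)^2
  fov <- outer(seq_len(d[1]), seq_len(d[2]),
               function(i, j) (i - cx)^2 + (j - cy)^2 <= rad2)
  X <- matrix(as.numeric(fov), npix, d[3])

  # per-subset projector slices, cached per geometry + subset count
  skey <- paste0(proj_key(d[1], d[2], sys$voxel_xy_mm, sys$n_angles,
                          sys$n_radial), "_sub", cfg$subsets)
  if (is.null(projector_cache[[skey]])) {
    projector_cache[[skey]] <- list(
      Ak = lapply(rows, function(rk) pr$P[rk, , drop = FALSE]),
      Atk = lapply(rows, function(rk) pr$Pt[, rk, drop = FALSE])
    )
  }
  Ak <- projector_cache[[skey]]$Ak
  Atk <- projector_cache[[skey]]$Atk
  mk <- lapply(rows, function(rk) m[rk, , drop = FALSE])
  afk <- if (use_af) lapply(rows, function(rk) afm[rk, , drop = FALSE]) else NULL
  addk <- lapply(rows, function(rk) addm[rk, , drop = FALSE])
  sens <- vector("list", cfg$subsets)
  for (k in seq_len(cfg$subsets)) {
    w <- if (use_af) afk[[k]] else matrix(1, length(rows[[k]]), d[3])
    sk <- as.matrix(Atk[[k]] %*% w)
    if (psf) sk <- smooth_img(sk)
    sens[[k]] <- sk
  }

  ll <- numeric(0)
  eps <- .Machine$double.xmin
  for (it in seq_len(cfg$iterations)) {
    for (k in seq_len(cfg$subsets)) {
      XP <- if (psf) smooth_img(X) else X
      fp <- as.matrix(Ak[[k]] %*% XP)
      ybar <- if (use_af) afk[[k]] * fp else fp
      ybar <- ybar + addk[[k]]
      ratio <- mk[[k]] / pmax(ybar, eps)
      ratio[ybar <= 0 & mk[[k]] <= 0] <- 0
      if (use_af) ratio <- ratio * afk[[k]]
      bp <- as.matrix(Atk[[k]] %*% ratio)
      if (psf) bp <- smooth_img(bp)
      sk <- sens[[k]]
      upd <- bp / pmax(sk, eps)
      upd[sk <= 0] <- 0
      X <- X * upd
    }
    if (track_loglik) {
      XP <- if (psf) smooth_img(X) else X
      fp <- as.matrix(pr$P %*% XP)
      ybar <- (if (use_af) afm * fp else fp) + addm
      ll <- c(ll, poisson_loglik(m, ybar))
    }
  }

  out <- voxel_grid(array(pmax(X, 0), d), grid$voxel_size_mm, grid$affine)
  if (cfg$out_voxel_mm < grid$voxel_size_mm[1] - 1e-9) out <- upsample_split(out)
  if (track_loglik) attr(out, "loglik") <- ll
  out
}

#' Data-driven scatter estimate
#'
#' Re-fits the simulator's scatter model from measured data: the scatter
#' shape is a broad radial Gaussian blur of the prompts, and its amplitude
#' is fitted by least squares against the prompts in the tail bins whose
#' rays miss the object (attenuation factor above 0.995). Randoms, when
#' supplied, are subtracted before fitting.
#'
#' @param prompts measured [sinogram()].
#' @param af attenuation-factor [sinogram()].
#' @param randoms_est optional randoms [sinogram()].
#' @return non-negative scatter [sinogram()], total bounded by the prompts
#'   total.
#' @export
estimate_scatter <- function(prompts, af, randoms_est = NULL) {
  p <- prompts$values
  if (!is.null(randoms_est)) p <- pmax(p - randoms_est$values, 0)
  b <- radial_blur(p, fwhm_bins = 8)
  tail <- af$values > 0.995
  scale <- if (sum(b[tail]^2) > 0) {
    max(0, sum(p[tail] * b[tail]) / sum(b[tail]^2))
  } else 0
  s <- scale * b
  tot_p <- sum(prompts$values)
  if (sum(s) > tot_p && sum(s) > 0) s <- s * (tot_p / sum(s))
  sinogram(array(s, dim(p)), kind = "scatter")
}
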