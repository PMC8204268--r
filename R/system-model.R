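## Parallel-beam, slice-stacked tomographic system.
##
## The projector is an explicit sparse matrix (Joseph-style ray sampling with
## bilinear footprints) shared by all slices, so forward and back projection
## are exact transposes of each other -- the matched-projector contract that
## OSEM and the adjoint tests rely on. The matrix is cached per geometry.

projector_cache <- new.env(parent = emptyenv())

#' Tomographic system model
#'
#' Parallel-beam geometry stacked slice by slice: radial bin width equals the
#' in-plane voxel size, angles span `[0, pi)`. An optional isotropic Gaussian
#' point-spread function (applied in image space before projection and after
#' back-projection, keeping the operator self-adjoint) models detector
#' resolution.
#'
#' @param n_angles number of projection angles (>= 8; divisible by the OSEM
#'   subset count used downstream).
#' @param n_radial number of radial bins.
#' @param n_slices number of axial slices.
#' @param voxel_xy_mm in-plane voxel/bin size in mm.
#' @param psf_fwhm_mm Gaussian PSF FWHM in mm (0 disables).
#' @return object of class `system_model`.
#' @export
system_model <- function(n_angles, n_radial, n_slices, voxel_xy_mm,
                         psf_fwhm_mm = 0) {
  stopifnot(n_angles >= 8, n_radial >= 4, n_slices >= 1, voxel_xy_mm > 0,
            psf_fwhm_mm >= 0)
  structure(
    list(n_angles = as.integer(n_angles), n_radial = as.integer(n_radial),
         n_slices = as.integer(n_slices), voxel_xy_mm = voxel_xy_mm,
         psf_fwhm_mm = psf_fwhm_mm, geometry = "parallel"),
    class = "system_model"
  )
}

#' Default system for an image grid
#'
#' @param g a [voxel_grid()] with equal x/y voxel size.
#' @param n_angles number of angles (default 56 = 4 x 14 subsets).
#' @param psf_fwhm_mm PSF FWHM in mm (default 4, scanner-like).
#' @return a [system_model()] whose radial extent covers the grid diagonal.
#' @export
default_system <- function(g, n_angles = 56L, psf_fwhm_mm = 4) {
  d <- dim(g$values)
  stopifnot(abs(g$voxel_size_mm[1] - g$voxel_size_mm[2]) < 1e-9)
  n_radial <- ceiling(1.2 * max(d[1], d[2]))
  if (n_radial %% 2 == 1) n_radial <- n_radial + 1
  system_model(n_angles, n_radial, d[3], g$voxel_size_mm[1], psf_fwhm_mm)
}

#' Sinogram container
#'
#' @param values array of dim (n_radial, n_angles, n_slices), non-negative.
#' @param kind one of `"prompts"`, `"trues"`, `"attenuation_factors"`,
#'   `"scatter"`, `"randoms"`, `"normalization"`.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(values, kind = "prompts") {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  kind <- match.arg(kind, c("prompts", "trues", "attenuation_factors",
                            "scatter", "randoms", "normalization"))
  if (kind == "attenuation_factors") {
    stopifnot(all(values > 0), all(values <= 1 + 1e-12))
  } else {
    stopifnot(min(values) >= 0)
  }
  structure(list(values = values, kind = kind), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram:%s> %s bins, total %.6g\n", x$kind,
              paste(dim(x$values), collapse = " x "), sum(x$values)))
  invisible(x)
}

proj_key <- function(n1, n2, v, n_angles, n_radial) {
  sprintf("p_%d_%d_%.6g_%d_%d", n1, n2, v, n_angles, n_radial)
}

## Build (or fetch) the 2D projection matrix: rows index (radial within
## angle), columns index in-plane pixels (i fastest). Entries are bilinear
## interpolation weights times the ray step length in mm.
projection_matrix <- function(n1, n2, v, n_angles, n_radial) {
  key <- proj_key(n1, n2, v, n_angles, n_radial)
  if (!is.null(projector_cache[[key]])) return(projector_cache[[key]])
  ds <- v / 2
  half_len <- 0.75 * max(n1, n2) * v
  s <- seq(-half_len, half_len, by = ds)
  r <- ((seq_len(n_radial)) - (n_radial + 1) / 2) * v
  cx <- (n1 + 1) / 2
  cy <- (n2 + 1) / 2
  ii <- jj <- ww <- rr <- vector("list", n_angles)
  for (a in seq_len(n_angles)) {
    th <- (a - 1) * pi / n_angles
    ct <- cos(th); st <- sin(th)
    # sample positions for all (radial, s) pairs
    X <- outer(r * ct, -s * st, "+") / v + cx   # n_radial x n_s, 1-based
    Y <- outer(r * st, s * ct, "+") / v + cy
    row_id <- rep(seq_len(n_radial), times = length(s)) + (a - 1L) * n_radial
    x <- as.vector(X); y <- as.vector(Y)
    i0 <- floor(x); j0 <- floor(y)
    fx <- x - i0; fy <- y - j0
    corners <- list(
      list(i = i0,     j = j0,     w = (1 - fx) * (1 - fy)),
      list(i = i0 + 1, j = j0,     w = fx * (1 - fy)),
      list(i = i0,     j = j0 + 1, w = (1 - fx) * fy),
      list(i = i0 + 1, j = j0 + 1, w = fx * fy)
    )
    ai <- aj <- aw <- ar <- vector("list", 4)
    for (cidx in 1:4) {
      cc <- corners[[cidx]]
      ok <- cc$i >= 1 & cc$i <= n1 & cc$j >= 1 & cc$j <= n2 & cc$w > 0
      ai[[cidx]] <- cc$i[ok]; aj[[cidx]] <- cc$j[ok]
      aw[[cidx]] <- cc$w[ok] * ds; ar[[cidx]] <- row_id[ok]
    }
    ii[[a]] <- unlist(ai); jj[[a]] <- unlist(aj)
    ww[[a]] <- unlist(aw); rr[[a]] <- unlist(ar)
  }
  P <- Matrix::sparseMatrix(
    i = unlist(rr),
    j = unlist(ii) + n1 * (unlist(jj) - 1L),
    x = unlist(ww),
    dims = c(n_angles * n_radial, n1 * n2)
  )
  obj <- list(P = P, Pt = Matrix::t(P))
  projector_cache[[key]] <- obj
  obj
}

check_sys_grid <- function(g, sys) {
  d <- dim(g$values)
  if (abs(g$voxel_size_mm[1] - sys$voxel_xy_mm) > 1e-9 ||
      abs(g$voxel_size_mm[2] - sys$voxel_xy_mm) > 1e-9 ||
      d[3] != sys$n_slices) {
    stop("grid/system geometry mismatch: grid ",
         paste(d, collapse = "x"), " @ ", g$voxel_size_mm[1],
         " mm vs system ", sys$n_radial, " bins x ", sys$n_slices,
         " slices @ ", sys$voxel_xy_mm, " mm")
  }
}

psf_sigma_vox <- function(g, sys) {
  sys$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / g$voxel_size_mm
}

#' Forward projection
#'
#' Line integrals of the (PSF-smoothed) activity along every parallel ray,
#' in units of activity x mm; linear in the input.
#'
#' @param activity non-negative [voxel_grid()].
#' @param sys a [system_model()] matching the grid.
#' @return [sinogram()] of kind `"trues"`.
#' @export
forward_project <- function(activity, sys) {
  check_sys_grid(activity, sys)
  d <- dim(activity$values)
  pr <- projection_matrix(d[1], d[2], sys$voxel_xy_mm, sys$n_angles,
                          sys$n_radial)
  vals <- activity$values
  if (sys$psf_fwhm_mm > 0) vals <- gauss_smooth3(vals, psf_sigma_vox(activity, sys))
  Y <- pr$P %*% matrix(vals, d[1] * d[2], d[3])
  sinogram(array(as.matrix(Y), c(sys$n_radial, sys$n_angles, sys$n_slices)),
           kind = "trues")
}

#' Back projection (adjoint of [forward_project()])
#'
#' @param sino a [sinogram()].
#' @param sys a [system_model()].
#' @param grid a [voxel_grid()] supplying the image geometry.
#' @return [voxel_grid()].
#' @export
back_project <- function(sino, sys, grid) {
  check_sys_grid(grid, sys)
  d <- dim(grid$values)
  pr <- projection_matrix(d[1], d[2], sys$voxel_xy_mm, sys$n_angles,
                          sys$n_radial)
  X <- pr$Pt %*% matrix(sino$values, sys$n_radial * sys$n_angles, d[3])
  out <- array(as.matrix(X), d)
  if (sys$psf_fwhm_mm > 0) out <- gauss_smooth3(out, psf_sigma_vox(grid, sys))
  voxel_grid(out, grid$voxel_size_mm, grid$affine)
}

#' Attenuation factor sinogram
#'
#' Per-bin survival probability `exp(-integral of mu)` along each ray. The
#' PSF is not applied to attenuation path lengths.
#'
#' @param mu_map [voxel_grid()] of linear attenuation coefficients per mm.
#' @param sys a [system_model()].
#' @return [sinogram()] of kind `"attenuation_factors"`, values in (0, 1].
#' @export
attenuation_factors <- function(mu_map, sys) {
  stopifnot(min(mu_map$values) >= 0)
  sys0 <- sys
  sys0$psf_fwhm_mm <- 0
  li <- forward_project(mu_map, sys0)
  sinogram(exp(-li$values), kind = "attenuation_factors")
}
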