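#' Voxel grids
#'
#' A `voxel_grid` is the universal image carrier of the package: a 3D array of
#' values together with a voxel size in mm and a 4x4 affine mapping 0-based
#' voxel indices `[i, j, k, 1]` to world coordinates in mm (RAS convention).
#' PET images, T1w images, attenuation maps and label volumes all travel as
#' voxel grids; labels use integer values with 0 meaning background/air.
#'
#' @param values numeric or integer 3D array.
#' @param voxel_size_mm positive numeric length 3, voxel edge lengths in mm.
#' @param affine optional 4x4 matrix; when `NULL` an axis-aligned affine is
#'   built that places the volume centre at the world origin, so that
#'   rotations about the image centre are rotations about world zero.
#' @return object of class `voxel_grid` with fields `values`, `voxel_size_mm`,
#'   `affine`.
#' @examples
#' g <- voxel_grid(array(1, c(8, 8, 8)), c(2, 2, 2))
#' dim(g$values)
#' @export
voxel_grid <- function(values, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    affine[1:3, 4] <- -voxel_size_mm * (dim(values) - 1) / 2
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(
    list(values = values, voxel_size_mm = voxel_size_mm, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %s voxels, %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
    paste(dim(x$values), collapse = " x "),
    x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' World coordinates of voxel centres
#'
#' @param g a [voxel_grid()].
#' @param idx0 matrix with 3 columns of 0-based voxel indices (may be
#'   fractional); when missing, all voxels of the grid are used.
#' @return N x 3 matrix of world coordinates in mm.
#' @export
grid_world_coords <- function(g, idx0 = NULL) {
  if (is.null(idx0)) {
    d <- dim(g$values)
    idx0 <- as.matrix(expand.grid(
      i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1, k = seq_len(d[3]) - 1
    ))
  }
  xyz <- idx0 %*% t(g$affine[1:3, 1:3])
  sweep(xyz, 2, g$affine[1:3, 4], "+")
}

#' World coordinate of the grid centre
#' @param g a [voxel_grid()].
#' @return length-3 numeric, mm.
#' @export
grid_centre_world <- function(g) {
  c0 <- (dim(g$values) - 1) / 2
  as.numeric(g$affine[1:3, 1:3] %*% c0 + g$affine[1:3, 4])
}

## Trilinear interpolation of a 3D array at fractional 0-based indices.
## Out-of-volume samples return `fill`.
interp_trilinear <- function(arr, idx0, fill = 0) {
  d <- dim(arr)
  i <- idx0[, 1]; j <- idx0[, 2]; k <- idx0[, 3]
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  inside <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    i0 <= d[1] - 1 & j0 <= d[2] - 1 & k0 <= d[3] - 1
  # clamp the upper neighbour so corner samples stay legal
  i1 <- pmax(pmin(i0 + 1, d[1] - 1), 0); j1 <- pmax(pmin(j0 + 1, d[2] - 1), 0)
  k1 <- pmax(pmin(k0 + 1, d[3] - 1), 0)
  i0c <- pmax(pmin(i0, d[1] - 1), 0); j0c <- pmax(pmin(j0, d[2] - 1), 0)
  k0c <- pmax(pmin(k0, d[3] - 1), 0)
  lin <- function(a, b, cc) 1 + a + d[1] * (b + d[2] * cc)
  v000 <- arr[lin(i0c, j0c, k0c)]; v100 <- arr[lin(i1, j0c, k0c)]
  v010 <- arr[lin(i0c, j1, k0c)]; v110 <- arr[lin(i1, j1, k0c)]
  v001 <- arr[lin(i0c, j0c, k1)]; v101 <- arr[lin(i1, j0c, k1)]
  v011 <- arr[lin(i0c, j1, k1)]; v111 <- arr[lin(i1, j1, k1)]
  out <- (1 - fk) * ((1 - fj) * ((1 - fi) * v000 + fi * v100) +
                       fj * ((1 - fi) * v010 + fi * v110)) +
    fk * ((1 - fj) * ((1 - fi) * v001 + fi * v101) +
            fj * ((1 - fi) * v011 + fi * v111))
  out[!inside] <- fill
  out
}

## Nearest-neighbour lookup at fractional 0-based indices; outside -> fill.
interp_nearest <- function(arr, idx0, fill = 0L) {
  d <- dim(arr)
  i <- round(idx0[, 1]); j <- round(idx0[, 2]); k <- round(idx0[, 3])
  inside <- i >= 0 & j >= 0 & k >= 0 & i <= d[1] - 1 & j <= d[2] - 1 &
    k <= d[3] - 1
  i <- pmax(pmin(i, d[1] - 1), 0); j <- pmax(pmin(j, d[2] - 1), 0)
  k <- pmax(pmin(k, d[3] - 1), 0)
  out <- arr[1 + i + d[1] * (j + d[2] * k)]
  out[!inside] <- fill
  out
}

#' Resample one grid onto another
#'
#' Samples `moving` at the voxel centres of `target`, optionally through a
#' rigid world transform. The transform follows the registration convention
#' of the package: it maps moving-image world coordinates onto target (fixed)
#' world coordinates, so sampling uses its inverse.
#'
#' @param moving,target [voxel_grid()] objects.
#' @param transform a [rigid_transform()] mapping moving world onto target
#'   world, or `NULL` for the identity.
#' @param method `"trilinear"` (default, for intensity images) or
#'   `"nearest"` (for label volumes).
#' @param fill value for samples falling outside `moving`.
#' @return a [voxel_grid()] on the geometry of `target`.
#' @export
resample_to_grid <- function(moving, target, transform = NULL,
                             method = c("trilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(target$values)
  # single homogeneous map: target index -> world -> (inverse transform)
  # -> moving world -> moving index
  M <- solve(moving$affine)
  if (!is.null(transform)) M <- M %*% solve(transform$matrix)
  M <- M %*% target$affine
  idx <- as.matrix(expand.grid(
    i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1, k = seq_len(d[3]) - 1
  ))
  src <- idx %*% t(M[1:3, 1:3])
  src <- sweep(src, 2, M[1:3, 4], "+")
  vals <- if (method == "trilinear") {
    interp_trilinear(moving$values, src, fill = fill)
  } else {
    interp_nearest(moving$values, src, fill = fill)
  }
  out <- array(vals, dim = d)
  if (method == "nearest" && is.integer(moving$values)) storage.mode(out) <- "integer"
  voxel_grid(out, target$voxel_size_mm, target$affine)
}

#' Split every voxel into eight equal voxels
#'
#' Upsampling by voxel subdivision without interpolation: each voxel becomes
#' a 2x2x2 block of voxels carrying the parent value, the voxel size is
#' halved and the affine is shifted so that every world position (in
#' particular every region centroid) is preserved. This is the
#' interpolation-free pathway for bringing PET images to the resolution of
#' the T1w-based region definitions.
#'
#' @param img a [voxel_grid()].
#' @return a [voxel_grid()] with doubled shape and halved voxel size.
#' @export
upsample_split <- function(img) {
  d <- dim(img$values)
  ix <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  iz <- rep(seq_len(d[3]), each = 2)
  out <- img$values[ix, iy, iz]
  A <- img$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] / 2
  # child voxel 2I sits a quarter parent-voxel before the parent centre
  A2[1:3, 4] <- A[1:3, 4] - A[1:3, 1:3] %*% rep(0.25, 3)
  voxel_grid(out, img$voxel_size_mm / 2, A2)
}

#' Block-mean downsampling
#'
#' Inverse of [upsample_split()] on values: averages `factor^3` blocks.
#' Shape must be divisible by `factor`.
#'
#' @param img a [voxel_grid()].
#' @param factor integer block edge (default 2).
#' @return a [voxel_grid()].
#' @export
downsample_block <- function(img, factor = 2L) {
  d <- dim(img$values)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  a <- array(img$values, c(factor, dn[1], factor, dn[2], factor, dn[3]))
  out <- apply(a, c(2, 4, 6), mean)
  A <- img$affine
  A2 <- A
  A2[1:3, 1:3] <- A[1:3, 1:3] * factor
  A2[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  voxel_grid(out, img$voxel_size_mm * factor, A2)
}

## Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
## Truncated (zero-padded) symmetric kernel: the operator is self-adjoint,
## which the matched projector/PSF contract relies on.
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-12) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    n <- d[ax]
    # banded convolution matrix (n x n), zero padding at the edges
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      ok <- idx + off >= 1 & idx + off <= n
      K[cbind(idx[ok], (idx + off)[ok])] <- k[off + r + 1]
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    a <- K %*% matrix(a, da[1], da[2] * da[3])
    dim(a) <- da
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Gaussian smoothing of a voxel grid
#'
#' @param g a [voxel_grid()].
#' @param fwhm_mm full width at half maximum of the isotropic Gaussian, mm.
#' @return smoothed [voxel_grid()].
#' @export
smooth_gauss <- function(g, fwhm_mm) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(g)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / g$voxel_size_mm
  voxel_grid(gauss_smooth3(g$values, sigma), g$voxel_size_mm, g$affine)
}

#' Read/write voxel grids as NIfTI-1
#'
#' Images are stored in the RAS world convention with the grid affine as the
#' sform/qform; `world = affine %*% c(i, j, k, 1)` with 0-based indices.
#'
#' @param g a [voxel_grid()].
#' @param path file path, typically ending in `.nii.gz`.
#' @return `write_nifti_grid` returns `path` invisibly; `read_nifti_grid`
#'   returns a [voxel_grid()].
#' @export
write_nifti_grid <- function(g, path) {
  img <- RNifti::asNifti(g$values)
  img <- RNifti::`sform<-`(img, structure(g$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  A <- structure(as.numeric(RNifti::xform(img)), dim = c(4L, 4L))
  vs <- sqrt(colSums(A[1:3, 1:3]^2))
  voxel_grid(array(as.numeric(img), dim = dim(img)), vs, A)
}

## Evaluate `code` under a local, restored RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a reproducible seed from a root seed and a label
#'
#' Deterministic 31-bit seed from a polynomial rolling hash of the label,
#' keyed by the root seed. This is the seed discipline of the pipelines:
#' every cell seed is `derive_seed(root_seed, cell_id)`, so no global RNG
#' state is consumed and every artifact is reproducible in isolation.
#'
#' @param root_seed integer root seed.
#' @param id character label (e.g. a design-cell id).
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(root_seed, id) {
  h <- as.double(root_seed %% 2147483647)
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}
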