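#' Rigid-body transforms
#'
#' Six-parameter rigid transform with a fixed convention: intrinsic
#' rotations about x, then y, then z (matrix `Rx %*% Ry %*% Rz`), applied
#' about a stated centre point in world mm, followed by a translation. As a
#' world map: `x -> R (x - c) + c + t`.
#'
#' @param translation_mm numeric length 3, mm.
#' @param rotation_deg numeric length 3, degrees about x, y, z.
#' @param centre_mm rotation centre in world mm (default the origin, which
#'   is the image centre for default-affine grids).
#' @return object of class `rigid_transform` with the derived 4x4 `matrix`.
#' @examples
#' t1 <- rigid_transform(c(5, 0, 0), c(0, 0, 10))
#' compose_rigid(t1, invert_rigid(t1))$matrix
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            centre_mm = c(0, 0, 0)) {
  t <- as.numeric(translation_mm); r <- as.numeric(rotation_deg)
  cen <- as.numeric(centre_mm)
  stopifnot(length(t) == 3, length(r) == 3, length(cen) == 3)
  R <- rot_xyz(r)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- cen + t - R %*% cen
  structure(
    list(translation_mm = t, rotation_deg = r, centre_mm = cen, matrix = M),
    class = "rigid_transform"
  )
}

rot_xyz <- function(deg) {
  a <- deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  Rx <- matrix(c(1, 0, 0, 0, ca[1], sa[1], 0, -sa[1], ca[1]), 3, 3)
  Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
  Rz <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

## Extract intrinsic x-y-z angles (deg) from a rotation matrix; valid for
## |pitch| < 90 deg.
rot_angles <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  g <- atan2(-R[1, 2], R[1, 1])
  c(a, b, g) * 180 / pi
}

#' Build a rigid transform from a 4x4 matrix
#'
#' @param M 4x4 rigid matrix (orthonormal rotation block, det +1).
#' @param centre_mm rotation centre used to express the parameters.
#' @return a [rigid_transform()].
#' @export
rigid_from_matrix <- function(M, centre_mm = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0) {
    stop("matrix is not a proper rigid transform")
  }
  cen <- as.numeric(centre_mm)
  t <- M[1:3, 4] - cen + R %*% cen
  rigid_transform(as.numeric(t), rot_angles(R), cen)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid> t = (%.3f, %.3f, %.3f) mm, r = (%.3f, %.3f, %.3f) deg\n",
              x$translation_mm[1], x$translation_mm[2], x$translation_mm[3],
              x$rotation_deg[1], x$rotation_deg[2], x$rotation_deg[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` applies `b` first, then `a` (matrix product
#' `a$matrix %*% b$matrix`); parameters of the result are expressed about
#' the centre of `a`.
#'
#' @param a,b,tr [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  rigid_from_matrix(a$matrix %*% b$matrix, centre_mm = a$centre_mm)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(tr) {
  rigid_from_matrix(solve(tr$matrix), centre_mm = tr$centre_mm)
}

#' Apply a rigid transform to world points
#'
#' @param tr a [rigid_transform()].
#' @param pts N x 3 matrix of world coordinates (mm).
#' @return N x 3 matrix.
#' @export
apply_rigid <- function(tr, pts) {
  out <- pts %*% t(tr$matrix[1:3, 1:3])
  sweep(out, 2, tr$matrix[1:3, 4], "+")
}

#' Perturbation specification
#'
#' Bounds of the uniform random perturbation of the MR position: each
#' translation component is Uniform(-t_bound, t_bound) mm and each rotation
#' Uniform(-r_bound, r_bound) degrees, all independent.
#'
#' @param t_bound_mm translation bound (default 10 mm).
#' @param r_bound_deg rotation bound (default 10 degrees).
#' @param seed integer RNG seed.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(t_bound_mm = 10, r_bound_deg = 10, seed = 1L) {
  stopifnot(t_bound_mm > 0, r_bound_deg > 0)
  structure(list(t_bound_mm = t_bound_mm, r_bound_deg = r_bound_deg,
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Draw a random rigid perturbation
#'
#' @param spec a [perturbation_spec()].
#' @param centre_mm rotation centre (the moving-image centre in world mm).
#' @return a [rigid_transform()] with all six parameters inside the bounds.
#' @export
draw_perturbation <- function(spec, centre_mm = c(0, 0, 0)) {
  u <- with_seed(spec$seed, stats::runif(6, -1, 1))
  rigid_transform(u[1:3] * spec$t_bound_mm, u[4:6] * spec$r_bound_deg,
                  centre_mm = centre_mm)
}

#' Perturb the position of an image
#'
#' Pre-multiplies the image affine by the transform matrix, moving the image
#' in world space while leaving the voxel values intact — the same mechanism
#' as editing a NIfTI affine.
#'
#' @param g a [voxel_grid()].
#' @param tr a [rigid_transform()].
#' @return a [voxel_grid()] with the updated affine.
#' @export
perturb_grid <- function(g, tr) {
  voxel_grid(g$values, g$voxel_size_mm, tr$matrix %*% g$affine)
}

#' Serialize rigid transforms
#'
#' The 4x4 matrix goes to a plain-text file (one row per line, world-mm
#' convention); parameters, convention tag and centre go to `<path>.json`.
#'
#' @param tr a [rigid_transform()].
#' @param path output path for the matrix text file.
#' @return `write_rigid` returns `path` invisibly; `read_rigid` a
#'   [rigid_transform()].
#' @export
write_rigid <- function(tr, path) {
  utils::write.table(tr$matrix, path, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(translation_mm = tr$translation_mm, rotation_deg = tr$rotation_deg,
         centre_mm = tr$centre_mm, convention = "intrinsic-xyz-about-centre"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rigid
#' @export
read_rigid <- function(path) {
  M <- as.matrix(utils::read.table(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rigid_from_matrix(unname(M), centre_mm = meta$centre_mm)
}
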