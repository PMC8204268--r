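#' Frame specification
#'
#' Describes one of the four emulated amyloid-PET frames: the early
#' (flow-like) and late (amyloid-specific) frames of an amyloid-negative and
#' an amyloid-positive scan. Activities are piecewise-constant per tissue
#' class in arbitrary units; the absolute scale is fixed by
#' `total_expected_counts`, the expected total of the noiseless forward
#' projection.
#'
#' @param frame_id one of `"early_neg"`, `"late_neg"`, `"early_pos"`,
#'   `"late_pos"`.
#' @param gm_activity,wm_activity,csf_activity tissue activities (a.u.).
#' @param total_expected_counts positive number of expected true events.
#' @return object of class `frame_spec`.
#' @export
frame_spec <- function(frame_id, gm_activity, wm_activity, csf_activity,
                       total_expected_counts) {
  frame_id <- match.arg(frame_id,
                        c("early_neg", "late_neg", "early_pos", "late_pos"))
  stopifnot(gm_activity >= 0, wm_activity >= 0, csf_activity >= 0,
            total_expected_counts >= 0)
  structure(
    list(frame_id = frame_id, gm_activity = gm_activity,
         wm_activity = wm_activity, csf_activity = csf_activity,
         total_expected_counts = total_expected_counts),
    class = "frame_spec"
  )
}

#' Default frame set
#'
#' The study conditions of the package: both early frames share one
#' flow-like grey/white pattern (GM:WM = 2), the late amyloid-negative frame
#' keeps strong cortical contrast (GM:WM = 4) and the late amyloid-positive
#' frame has lost grey/white contrast (GM:WM = 1.05). CSF is fixed at 5% of
#' white matter in all frames. Expected counts are desk-scale: 1e6 for the
#' short early frames and 2e6 for the 30-minute-analogue late frames, so
#' that the 5% bootstrap level lands deep in the noise-limited regime.
#'
#' @return named list of [frame_spec()] objects.
#' @export
default_frames <- function() {
  list(
    early_neg = frame_spec("early_neg", 2.0, 1.0, 0.05, 1e6),
    late_neg  = frame_spec("late_neg",  4.0, 1.0, 0.05, 2e6),
    early_pos = frame_spec("early_pos", 2.0, 1.0, 0.05, 1e6),
    late_pos  = frame_spec("late_pos",  1.05, 1.0, 0.05, 2e6)
  )
}

## Nine analysis ROIs (the grey-matter-only set plus cerebellar white
## matter used for registration-precision reporting).
#' Names of the analysis regions
#' @return character vector of the nine per-region analysis ROIs.
#' @export
analysis_roi_names <- function() {
  c("ACG", "MCG", "PCG", "HPC", "PRC", "PRT", "TMP", "CRB_GM", "CRB_WM")
}

phantom_region_table <- function() {
  tibble::tibble(
    label_id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L),
    name = c("ACG", "MCG", "PCG", "HPC", "PRC", "PRT", "TMP",
             "CRB_GM", "CRB_WM", "CTX", "WM", "CSF", "BONE"),
    role = c("other", "other", "other", "other", "target", "other", "other",
             "reference", "other", "other", "other", "other", "other"),
    tissue = c("GM", "GM", "GM", "GM", "GM", "GM", "GM",
               "GM", "WM", "GM", "WM", "CSF", "bone")
  )
}

## Ellipsoid membership in per-axis normalised coordinates.
.ell <- function(u, centre, semi) {
  ((u[, 1] - centre[1]) / semi[1])^2 +
    ((u[, 2] - centre[2]) / semi[2])^2 +
    ((u[, 3] - centre[3]) / semi[3])^2 <= 1
}

## Analytic anatomy evaluated at arbitrary world coordinates (mm), given the
## per-axis half field of view. Geometry is parametric (nested ellipsoids)
## and scales with the FOV, so the same anatomy renders on any grid.
phantom_labels_at <- function(world, half_fov) {
  u <- sweep(world, 2, half_fov, "/")
  lab <- integer(nrow(u))
  # head-like nested shells, distinctly anisotropic in all three axes
  # (long front-to-back, flat top-to-bottom): every rotation axis changes
  # the image, which is what makes rotations observable to the registration
  skull_out <- .ell(u, c(0, 0, 0), c(0.80, 0.90, 0.70))
  skull_in  <- .ell(u, c(0, 0, 0), c(0.74, 0.84, 0.64))
  brain_out <- .ell(u, c(0, 0, 0), c(0.68, 0.78, 0.58))
  wm_out    <- .ell(u, c(0, 0, 0), c(0.58, 0.68, 0.48))
  lab[skull_out & !skull_in] <- 13L                       # bone
  lab[skull_in & !brain_out] <- 12L                       # subarachnoid CSF
  lab[brain_out & !wm_out] <- 10L                         # cortical ribbon
  lab[wm_out] <- 11L                                      # cerebral WM
  # ventricles
  vent <- .ell(u, c(0.17, 0.02, 0.05), c(0.095, 0.19, 0.10)) |
    .ell(u, c(-0.17, 0.02, 0.05), c(0.095, 0.19, 0.10))
  lab[vent & lab == 11L] <- 12L
  # cerebellum: GM shell around a WM core, fully embedded in cerebral WM so
  # the reference region couples to white matter, not to air
  crb_out <- .ell(u, c(0, -0.18, -0.24), c(0.21, 0.19, 0.14))
  crb_in  <- .ell(u, c(0, -0.18, -0.24), c(0.165, 0.145, 0.10))
  lab[crb_out & lab == 11L] <- 8L
  lab[crb_in & lab %in% c(8L, 11L)] <- 9L
  # hippocampus-analogue: small GM blob in the white matter (one-sided,
  # breaking mirror symmetry)
  hpc <- .ell(u, c(-0.34, 0.22, -0.12), rep(0.095, 3))
  lab[hpc & lab == 11L] <- 4L
  # cortical patches carved out of the ribbon
  carve <- function(lab, centre, r, id) {
    m <- .ell(u, centre, rep(r, 3)) & lab == 10L
    lab[m] <- id
    lab
  }
  lab <- carve(lab, c(0, -0.60, 0.35), 0.17, 5L)    # PRC (target)
  lab <- carve(lab, c(0, 0.73, 0.10), 0.125, 1L)    # ACG
  lab <- carve(lab, c(0, 0.15, 0.55), 0.125, 2L)    # MCG
  lab <- carve(lab, c(0, -0.35, 0.50), 0.125, 3L)   # PCG
  # lobes from the remaining ribbon (single-sided to stay one blob each)
  prt <- lab == 10L & u[, 3] >= 0.35 & u[, 1] >= 0.12
  lab[prt] <- 6L
  tmp <- lab == 10L & u[, 3] <= -0.21 & u[, 1] >= 0.15
  lab[tmp] <- 7L
  lab
}

#' Generate a seeded digital brain phantom
#'
#' Builds the parcellation, attenuation map and high-resolution T1w-like
#' image that the registration-uncertainty analysis runs on. Anatomy is a
#' nested-ellipsoid head: skull bone shell, subarachnoid CSF, a cortical
#' grey-matter ribbon partitioned into named regions (anterior/middle/
#' posterior cingulate patches, precuneus target, parietal and temporal
#' lobes, residual cortex), cerebral white matter with ventricles, a
#' hippocampus-analogue blob, and a cerebellar grey-matter shell around a
#' cerebellar white-matter core. The attenuation map is piecewise constant
#' (soft tissue 0.0096/mm, bone 0.0151/mm, air 0 at 511 keV). The T1w image
#' renders the same analytic anatomy on a grid with half the voxel size,
#' with additive Gaussian noise at 1% of the white-matter intensity.
#'
#' @param seed integer; identical seeds give bit-identical phantoms.
#' @param grid_shape integer length 3, each at least 16.
#' @param voxel_size_mm numeric length 3 (default 2 mm isotropic).
#' @return list of class `pet_phantom` with elements `labels` (PET-grid
#'   parcellation), `regions` (tibble: label_id, name, role, tissue),
#'   `mu_map`, `t1w`, and `labels_hr` (the parcellation on the T1w grid,
#'   used for label propagation).
#' @examples
#' ph <- make_phantom(1, c(32, 32, 32), c(2, 2, 2))
#' table(ph$labels$values)[1:4]
#' @export
make_phantom <- function(seed = 1L, grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(2, 2, 2)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L))
  half_fov <- grid_shape * voxel_size_mm / 2
  regions <- phantom_region_table()

  render <- function(shape, vs) {
    g <- voxel_grid(array(0L, shape), vs)
    w <- grid_world_coords(g)
    lab <- phantom_labels_at(w, half_fov)
    g$values <- array(as.integer(lab), shape)
    g
  }
  labels <- render(grid_shape, voxel_size_mm)

  counts <- table(factor(labels$values, levels = regions$label_id))
  # an analysis ROI below ~10 voxels is useless for overlap statistics
  floor_n <- ifelse(regions$name %in% analysis_roi_names(), 10L, 1L)
  bad <- regions$name[as.integer(counts) < floor_n]
  if (length(bad) > 0) {
    stop("phantom grid too small: region(s) missing or too small: ",
         paste(bad, collapse = ", "))
  }

  mu <- array(0, grid_shape)
  mu[labels$values %in% c(1:12)] <- 0.0096
  mu[labels$values == 13L] <- 0.0151
  mu_map <- voxel_grid(mu, voxel_size_mm, labels$affine)

  labels_hr <- render(grid_shape * 2L, voxel_size_mm / 2)
  # T1w tissue intensities indexed by label + 1 (WM bright, GM mid, CSF dark)
  t1w_int <- c(0,                      # air
               rep(0.62, 8),          # GM regions 1..8
               1.0,                   # CRB_WM
               0.62,                  # CTX
               1.0,                   # WM
               0.22,                  # CSF
               0.30)                  # bone
  vals <- t1w_int[as.integer(labels_hr$values) + 1L]
  noise <- with_seed(derive_seed(seed, "t1w-noise"),
                     stats::rnorm(length(vals), sd = 0.01))
  t1w <- voxel_grid(array(pmax(vals + noise, 0), dim(labels_hr$values)),
                    labels_hr$voxel_size_mm, labels_hr$affine)

  structure(
    list(labels = labels, regions = regions, mu_map = mu_map, t1w = t1w,
         labels_hr = labels_hr, seed = as.integer(seed)),
    class = "pet_phantom"
  )
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("<pet_phantom> seed %d, %s voxels @ %.3g mm, %d regions\n",
              x$seed, paste(dim(x$labels$values), collapse = "x"),
              x$labels$voxel_size_mm[1], nrow(x$regions)))
  invisible(x)
}

#' Piecewise-constant activity map for one frame
#'
#' Assigns each voxel the tissue activity of its region (GM/WM/CSF; bone and
#' air carry no activity) and rescales so that the noiseless forward
#' projection through `sys` yields `total_expected_counts` expected events.
#'
#' @param labels parcellation [voxel_grid()].
#' @param regions region table as returned in [make_phantom()].
#' @param frame a [frame_spec()].
#' @param sys a [system_model()]; default `NULL` builds the default system
#'   for the label grid.
#' @return activity [voxel_grid()] (expected counts per mm of ray per voxel
#'   unit, arbitrary-but-calibrated units).
#' @export
make_activity <- function(labels, regions, frame, sys = NULL) {
  stopifnot(inherits(frame, "frame_spec"))
  tissue_act <- c(GM = frame$gm_activity, WM = frame$wm_activity,
                  CSF = frame$csf_activity, bone = 0, air = 0)
  act_by_label <- numeric(max(regions$label_id) + 1L)
  act_by_label[regions$label_id + 1L] <- tissue_act[regions$tissue]
  vals <- act_by_label[as.integer(labels$values) + 1L]
  act <- voxel_grid(array(vals, dim(labels$values)),
                    labels$voxel_size_mm, labels$affine)
  if (frame$total_expected_counts <= 0 || sum(vals) == 0) {
    act$values[] <- 0
    return(act)
  }
  if (is.null(sys)) sys <- default_system(act)
  tot <- sum(forward_project(act, sys)$values)
  act$values <- act$values * (frame$total_expected_counts / tot)
  act
}
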