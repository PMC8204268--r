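#' Experiment design
#'
#' The full factorial design of the uncertainty analysis. The default is the
#' paper-scale bookkeeping design (4 frames, 3 correction modes, 1-3 OSEM
#' iterations, 14 subsets, count levels 5/15/30/60%, 50 bootstrap replicates,
#' two output voxel sizes, MR-position perturbation on, and one extra
#' reconstruction per attenuation-corrected image for aligning the
#' attenuation map). [reduced_design()] gives the desk-scale profile the
#' simulation pipelines run by default.
#'
#' @param frames named list of [frame_spec()]s.
#' @param modes character subset of NAC/AC/QNT.
#' @param iteration_grid integer OSEM iteration counts.
#' @param subsets OSEM subsets.
#' @param count_levels bootstrap count levels in (0, 1].
#' @param n_bootstrap replicates per cell.
#' @param engines registration engine names (>= 1; `"nmi"` is in-repo).
#' @param voxel_sizes output voxel sizes in mm (subset of 2, 1).
#' @param perturb randomly perturb the MR position per replicate.
#' @param mumap_align_recons count one extra reconstruction per AC/QNT
#'   uncertainty image (and per count-level bootstrap) for attenuation-map
#'   alignment bookkeeping.
#' @param grid_shape phantom grid for simulation runs.
#' @param scatter_fraction,randoms_fraction simulation background fractions.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(frames = default_frames(),
                              modes = c("NAC", "AC", "QNT"),
                              iteration_grid = 1:3,
                              subsets = 14L,
                              count_levels = c(0.05, 0.15, 0.30, 0.60),
                              n_bootstrap = 50L,
                              engines = "nmi",
                              voxel_sizes = c(2.0, 1.0),
                              perturb = TRUE,
                              mumap_align_recons = TRUE,
                              grid_shape = c(64L, 64L, 64L),
                              scatter_fraction = 0.2,
                              randoms_fraction = 0.1) {
  modes <- match.arg(modes, c("NAC", "AC", "QNT"), several.ok = TRUE)
  stopifnot(length(frames) >= 1, all(count_levels > 0), all(count_levels <= 1),
            n_bootstrap >= 1, length(engines) >= 1,
            all(voxel_sizes %in% c(2.0, 1.0)))
  structure(
    list(frames = frames, modes = modes,
         iteration_grid = as.integer(iteration_grid),
         subsets = as.integer(subsets), count_levels = count_levels,
         n_bootstrap = as.integer(n_bootstrap), engines = engines,
         voxel_sizes = voxel_sizes, perturb = isTRUE(perturb),
         mumap_align_recons = isTRUE(mumap_align_recons),
         grid_shape = as.integer(grid_shape),
         scatter_fraction = scatter_fraction,
         randoms_fraction = randoms_fraction),
    class = "experiment_design"
  )
}

#' @rdname experiment_design
#' @param ... overrides passed to [experiment_design()].
#' @export
reduced_design <- function(...) {
  args <- list(...)
  defaults <- list(
    frames = default_frames()[c("late_neg", "late_pos")],
    modes = "AC",
    iteration_grid = 2L,
    count_levels = c(0.05, 0.60),
    n_bootstrap = 5L,
    voxel_sizes = 2.0,
    grid_shape = c(64L, 64L, 64L)
  )
  defaults[names(args)] <- args
  do.call(experiment_design, defaults)
}

#' Enumerate the reconstruction-parameter analysis
#'
#' Counts the bookkeeping of the reconstruction-parameter arm by explicit
#' cell enumeration: independently resampled list-mode datasets (one per
#' frame x iteration setting x bootstrap), uncertainty images (one per
#' dataset x correction mode), and attenuation-map-alignment
#' reconstructions (one per dataset x attenuation-corrected mode).
#'
#' @param d an [experiment_design()].
#' @return tibble with one row: `n_bootstrap_datasets`,
#'   `n_uncertainty_images`, `n_mumap_recons`, `n_total_images`.
#' @export
enumerate_recon_param_design <- function(d) {
  datasets <- tidyr::expand_grid(
    frame = names(d$frames),
    iterations = d$iteration_grid,
    bootstrap = seq_len(d$n_bootstrap)
  )
  images <- tidyr::expand_grid(datasets, mode = d$modes)
  mumap <- if (d$mumap_align_recons) {
    tidyr::expand_grid(datasets,
                       mode = intersect(d$modes, c("AC", "QNT")))
  } else datasets[0, ]
  tibble::tibble(
    n_bootstrap_datasets = nrow(datasets),
    n_uncertainty_images = nrow(images),
    n_mumap_recons = nrow(mumap),
    n_total_images = nrow(images) + nrow(mumap)
  )
}

#' Enumerate the count-level analysis
#'
#' One bootstrap dataset per frame x count level x bootstrap replicate; each
#' dataset is reconstructed once per output voxel size, plus one
#' attenuation-map-alignment reconstruction per dataset when enabled.
#'
#' @param d an [experiment_design()].
#' @return tibble with one row: `n_bootstrap_datasets`, `n_recon_images`,
#'   `n_mumap_recons`, `n_total_images`.
#' @export
enumerate_count_level_design <- function(d) {
  datasets <- tidyr::expand_grid(
    frame = names(d$frames),
    count_level = d$count_levels,
    bootstrap = seq_len(d$n_bootstrap)
  )
  recons <- tidyr::expand_grid(datasets, voxel = d$voxel_sizes)
  mumap <- if (d$mumap_align_recons) datasets else datasets[0, ]
  tibble::tibble(
    n_bootstrap_datasets = nrow(datasets),
    n_recon_images = nrow(recons),
    n_mumap_recons = nrow(mumap),
    n_total_images = nrow(recons) + nrow(mumap)
  )
}
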