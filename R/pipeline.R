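## Registration engine registry: an engine is
## function(fixed, moving, init) -> registration_result. The in-repo engine
## is NMI direction-set; external tools can be plugged in via an adapter
## without touching the pipelines.

engine_registry <- new.env(parent = emptyenv())

#' Registration engines
#'
#' @param name engine name.
#' @param fun function `(fixed, moving, init)` returning a
#'   [registration_result()].
#' @return `register_engine` returns `name` invisibly; `get_engine` the
#'   engine function; `list_engines` the registered names.
#' @export
register_engine <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  engine_registry[[name]] <- fun
  invisible(name)
}

#' @rdname register_engine
#' @export
get_engine <- function(name) {
  if (identical(name, "nmi")) {
    return(function(fixed, moving, init = NULL) {
      register_rigid(fixed, moving, init = init)
    })
  }
  fun <- engine_registry[[name]]
  if (is.null(fun)) stop("unknown registration engine: ", name)
  fun
}

#' @rdname register_engine
#' @export
list_engines <- function() union("nmi", ls(engine_registry))

cortex_label_ids <- function() c(1L, 2L, 3L, 5L, 6L, 7L, 10L)

roi_dice <- function(ref_vals, boot_vals, regions) {
  rois <- analysis_roi_names()
  ids <- regions$label_id[match(rois, regions$name)]
  out <- vapply(ids, function(id) {
    ra <- ref_vals == id
    rb <- boot_vals == id
    if (!any(ra) && !any(rb)) return(NA_real_)
    dice(ra, rb)
  }, 1)
  ctx <- cortex_label_ids()
  c(stats::setNames(out, rois),
    cortex = dice(ref_vals %in% ctx, boot_vals %in% ctx))
}

## One-off per-frame setup: activity, full-count list-mode, attenuation
## factors, randoms expectation, reference reconstruction + registration.
frame_setup <- function(ph, frame, sys_sim, sys_rec, d, root_seed, engine_fun) {
  act <- make_activity(ph$labels, ph$regions, frame, sys_sim)
  sim <- simulate_prompts(act, ph$mu_map, sys_sim,
                          scatter_fraction = d$scatter_fraction,
                          randoms_fraction = d$randoms_fraction,
                          seed = derive_seed(root_seed, paste0("sim|", frame$frame_id)))
  prompts <- bin_events(sim$listmode)
  cfg_ref <- recon_config("AC", iterations = 2L, subsets = d$subsets)
  ref_recon <- osem(prompts, sys_rec, cfg_ref, ph$labels, af = sim$af,
                    randoms_est = sim$randoms)
  ref_reg <- engine_fun(ref_recon, ph$t1w, NULL)
  target_hr <- upsample_split(ref_recon)
  ref_labels <- propagate_labels(ph$labels_hr, ref_reg$transform, target_hr)
  list(activity = act, lm = sim$listmode, af = sim$af, randoms = sim$randoms,
       prompts = prompts, ref_recon = ref_recon, ref_reg = ref_reg,
       target_hr = target_hr, ref_label_vals = as.integer(ref_labels$values))
}

#' Run the registration-uncertainty analysis
#'
#' End-to-end seeded pipeline: phantom, simulation, per-cell bootstrap
#' resampling, OSEM reconstruction, (optional) random MR-position
#' perturbation, rigid registration, label propagation and Dice against the
#' full-count gold-standard registration of each frame. Deterministic for a
#' fixed root seed; cells already present in `cache_dir` are reused.
#'
#' @param d an [experiment_design()] (typically [reduced_design()]).
#' @param root_seed integer; every per-cell seed is derived from it.
#' @param phantom optional pre-built [make_phantom()] output.
#' @param cache_dir optional directory for per-cell result caching
#'   (resume-safe: interrupting and resuming yields identical tables).
#' @param verbose print per-cell progress.
#' @return list of class `uncertainty_run`: `samples` (tibble: frame, mode,
#'   iterations, count_level, engine, replicate, roi, dice, converged),
#'   `matrix` (the [sd_matrix()] summary), `records` (run bookkeeping),
#'   `transforms` (per-cell registration + perturbation, reused by
#'   [run_suvr_propagation()]), `frames` (per-frame reference data),
#'   `phantom`, `design`.
#' @export
run_uncertainty_analysis <- function(d, root_seed = 1L, phantom = NULL,
                                     cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(d, "experiment_design"))
  if (is.null(phantom)) {
    phantom <- make_phantom(derive_seed(root_seed, "phantom"), d$grid_shape)
  }
  sys_sim <- default_system(phantom$labels, psf_fwhm_mm = 4)
  sys_rec <- default_system(phantom$labels, psf_fwhm_mm = 0)
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }

  cells <- tidyr::expand_grid(
    frame = names(d$frames), mode = d$modes, iterations = d$iteration_grid,
    count_level = d$count_levels, engine = d$engines,
    replicate = seq_len(d$n_bootstrap)
  )

  frames_data <- list()
  rows <- vector("list", nrow(cells))
  records <- vector("list", nrow(cells))
  transforms <- list()
  t1w_centre <- grid_centre_world(phantom$t1w)

  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    engine_fun <- get_engine(cell$engine)
    if (is.null(frames_data[[cell$frame]])) {
      frames_data[[cell$frame]] <- frame_setup(
        phantom, d$frames[[cell$frame]], sys_sim, sys_rec, d, root_seed,
        engine_fun)
    }
    fd <- frames_data[[cell$frame]]
    cell_id <- sprintf("f=%s|m=%s|it=%d|cl=%g|e=%s|b=%d",
                       cell$frame, cell$mode, cell$iterations,
                       cell$count_level, cell$engine, cell$replicate)
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0("cell_", gsub("[^A-Za-z0-9._=-]", "_", cell_id), ".rds"))
    } else NULL

    if (!is.null(cache_file) && file.exists(cache_file)) {
      res <- readRDS(cache_file)
    } else {
      seed_boot <- derive_seed(root_seed, paste0(cell_id, "|boot"))
      seed_pert <- derive_seed(root_seed, paste0(cell_id, "|pert"))
      lm_b <- bootstrap_listmode(fd$lm, cell$count_level, seed_boot)
      prompts_b <- bin_events(lm_b)
      randoms_b <- sinogram(fd$randoms$values * cell$count_level,
                            kind = "randoms")
      cfg <- recon_config(cell$mode, iterations = cell$iterations,
                          subsets = d$subsets)
      scatter_b <- if (cell$mode == "QNT") {
        estimate_scatter(prompts_b, fd$af, randoms_b)
      } else NULL
      recon_b <- osem(prompts_b, sys_rec, cfg, phantom$labels,
                      af = fd$af, scatter_est = scatter_b,
                      randoms_est = randoms_b)
      pert <- if (d$perturb) {
        draw_perturbation(perturbation_spec(seed = seed_pert),
                          centre_mm = t1w_centre)
      } else NULL
      moving <- if (is.null(pert)) phantom$t1w else perturb_grid(phantom$t1w, pert)
      reg <- engine_fun(recon_b, moving, NULL)
      lab_src <- if (is.null(pert)) phantom$labels_hr else
        perturb_grid(phantom$labels_hr, pert)
      boot_labels <- propagate_labels(lab_src, reg$transform, fd$target_hr)
      dv <- roi_dice(fd$ref_label_vals, as.integer(boot_labels$values),
                     phantom$regions)
      res <- list(dice = dv, transform = reg$transform, pert = pert,
                  converged = reg$converged,
                  final_similarity = reg$final_similarity,
                  seeds = c(boot = seed_boot, pert = seed_pert))
      if (!is.null(cache_file)) saveRDS(res, cache_file)
    }

    rows[[ci]] <- tibble::tibble(
      frame = cell$frame, mode = cell$mode, iterations = cell$iterations,
      count_level = cell$count_level, engine = cell$engine,
      replicate = cell$replicate, roi = names(res$dice),
      dice = unname(res$dice), converged = res$converged
    )
    records[[ci]] <- tibble::tibble(
      cell_id = cell_id, frame = cell$frame, mode = cell$mode,
      iterations = cell$iterations, count_level = cell$count_level,
      engine = cell$engine, replicate = cell$replicate,
      seed_boot = res$seeds[["boot"]], seed_pert = res$seeds[["pert"]],
      converged = res$converged, final_similarity = res$final_similarity
    )
    transforms[[cell_id]] <- res[c("transform", "pert", "converged")]
    if (verbose) message(cell_id, "  NMI=", round(res$final_similarity, 4))
  }

  samples <- dplyr::bind_rows(rows)
  structure(
    list(samples = samples, matrix = sd_matrix(samples),
         records = dplyr::bind_rows(records), transforms = transforms,
         frames = frames_data, phantom = phantom, design = d,
         root_seed = root_seed,
         sys = list(sim = sys_sim, rec = sys_rec)),
    class = "uncertainty_run"
  )
}

#' @export
print.uncertainty_run <- function(x, ...) {
  cat(sprintf("<uncertainty_run> %d samples, %d cells, root seed %d\n",
              nrow(x$samples), nrow(x$matrix$average), x$root_seed))
  invisible(x)
}

#' Propagate registration uncertainty into SUVr
#'
#' Reconstructs a single fixed quantitative PET per frame (an
#' attenuation-corrected reconstruction of a dedicated 30%-count bootstrap,
#' the clinical-static analogue) and samples it with every replicate's
#' propagated parcellation from an [run_uncertainty_analysis()] result, so
#' the observed variability comes from registration imprecision only. SUVr
#' (target over reference region) is computed with and without
#' iterative-Yang partial volume correction, and summarised as the
#' coefficient of variation per frame x count level x PVC flag. Failed
#' registrations are excluded.
#'
#' @param run an `uncertainty_run`.
#' @param pvc_fwhm_mm PVC PSF FWHM in mm (default 4.5).
#' @param quant_level count level of the quantitative PET (default 0.30).
#' @return list with tibbles `table` (per-replicate SUVr) and `cov`
#'   (frame, count_level, pvc, n, suvr_mean, cov).
#' @export
run_suvr_propagation <- function(run, pvc_fwhm_mm = 4.5, quant_level = 0.30) {
  stopifnot(inherits(run, "uncertainty_run"))
  d <- run$design
  ph <- run$phantom
  target_id <- ph$regions$label_id[ph$regions$role == "target"][1]
  ref_id <- ph$regions$label_id[ph$regions$role == "reference"][1]

  out <- list()
  for (fr in names(run$frames)) {
    fd <- run$frames[[fr]]
    lm_q <- bootstrap_listmode(fd$lm, quant_level,
                               derive_seed(run$root_seed, paste0("quant|", fr)))
    cfg <- recon_config("AC", iterations = 2L, subsets = d$subsets)
    quant <- osem(bin_events(lm_q), run$sys$rec, cfg, ph$labels, af = fd$af,
                  randoms_est = sinogram(fd$randoms$values * quant_level,
                                         kind = "randoms"))
    rec <- dplyr::filter(run$records, frame == fr)
    for (ri in seq_len(nrow(rec))) {
      tr <- run$transforms[[rec$cell_id[ri]]]
      if (!tr$converged) next
      lab_src <- if (is.null(tr$pert)) ph$labels_hr else
        perturb_grid(ph$labels_hr, tr$pert)
      labs <- propagate_labels(lab_src, tr$transform, quant)
      s0 <- suvr(quant, labs, target_id, ref_id, pvc_applied = FALSE)
      pet_pvc <- yang_pvc(quant, labs, psf_fwhm_mm = pvc_fwhm_mm)
      s1 <- suvr(pet_pvc, labs, target_id, ref_id, pvc_applied = TRUE)
      out[[length(out) + 1L]] <- dplyr::bind_rows(s0, s1) |>
        dplyr::mutate(frame = fr, count_level = rec$count_level[ri],
                      replicate = rec$replicate[ri], mode = rec$mode[ri],
                      iterations = rec$iterations[ri])
    }
  }
  table <- dplyr::bind_rows(out)
  cov <- table |>
    dplyr::group_by(frame, count_level, pvc = pvc_applied) |>
    dplyr::summarise(n = dplyr::n(), suvr_mean = mean(suvr),
                     cov = coeff_var(suvr), .groups = "drop")
  list(table = table, cov = cov)
}

#' Write run result tables as CSV
#'
#' Deterministic tidy exports: per-replicate Dice samples, per-ROI SDs, and
#' cell averages. Re-running the same seeded analysis reproduces the files
#' byte for byte.
#'
#' @param run an `uncertainty_run`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_result_tables <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "dice_samples.csv")
  f2 <- file.path(dir, "dice_sd_per_roi.csv")
  f3 <- file.path(dir, "dice_sd_average.csv")
  utils::write.csv(run$samples, f1, row.names = FALSE)
  utils::write.csv(tidy(run$matrix), f2, row.names = FALSE)
  utils::write.csv(run$matrix$average, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
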