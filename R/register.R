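#' Normalised mutual information
#'
#' `NMI = (H(F) + H(M)) / H(F, M)` from the joint histogram of the two
#' images over the overlap mask (voxels where both images exceed 0,
#' excluding background), with equal-width bins spanning each image's range
#' inside the mask. Values lie in `[1, 2]`; 2 means identical (up to a
#' bin-preserving intensity map).
#'
#' @param fixed,moving_resampled [voxel_grid()]s on the same grid.
#' @param bins number of histogram bins per image (>= 8, default 64).
#' @return scalar NMI.
#' @export
nmi <- function(fixed, moving_resampled, bins = 64L) {
  stopifnot(bins >= 8)
  f <- as.vector(fixed$values)
  m <- as.vector(moving_resampled$values)
  stopifnot(length(f) == length(m))
  ok <- f > 0 & m > 0
  if (!any(ok)) stop("empty overlap between images: NMI undefined")
  nmi_masked(f[ok], m[ok], bins)
}

nmi_masked <- function(f, m, bins) {
  fr <- range(f); mr <- range(m)
  fb <- if (fr[2] > fr[1]) {
    pmin(floor((f - fr[1]) / (fr[2] - fr[1]) * bins), bins - 1L)
  } else rep(0L, length(f))
  mb <- if (mr[2] > mr[1]) {
    pmin(floor((m - mr[1]) / (mr[2] - mr[1]) * bins), bins - 1L)
  } else rep(0L, length(m))
  joint <- tabulate(1L + fb + bins * mb, nbins = bins * bins)
  nmi_from_joint(joint, bins)
}

nmi_from_joint <- function(joint, bins) {
  p <- joint / sum(joint)
  pj <- p[p > 0]
  hj <- -sum(pj * log(pj))
  pf <- rowSums(matrix(p, bins, bins))
  pm <- colSums(matrix(p, bins, bins))
  hf <- -sum(pf[pf > 0] * log(pf[pf > 0]))
  hm <- -sum(pm[pm > 0] * log(pm[pm > 0]))
  if (hj == 0) return(2)
  (hf + hm) / hj
}

## Downsample a grid by an integer factor where possible (trim to a
## divisible shape first); used for the multi-resolution pyramid.
pyramid_level <- function(g, factor) {
  if (factor == 1) return(g)
  d <- dim(g$values)
  dd <- (d %/% factor) * factor
  if (any(dd < factor)) return(g)
  gg <- voxel_grid(g$values[seq_len(dd[1]), seq_len(dd[2]), seq_len(dd[3]),
                            drop = FALSE],
                   g$voxel_size_mm, g$affine)
  downsample_block(gg, factor)
}

#' Registration result
#'
#' @param transform recovered [rigid_transform()] mapping moving world
#'   coordinates onto fixed world coordinates.
#' @param final_similarity NMI at the optimum.
#' @param converged logical; `FALSE` when the optimizer exhausted its
#'   evaluation budget (recorded, not raised, so failed registrations can be
#'   excluded downstream).
#' @param n_evaluations number of cost evaluations spent.
#' @return object of class `registration_result`.
#' @export
registration_result <- function(transform, final_similarity, converged,
                                n_evaluations) {
  structure(list(transform = transform, final_similarity = final_similarity,
                 converged = converged, n_evaluations = n_evaluations),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration> NMI %.5f, %s, %d evaluations\n",
              x$final_similarity,
              if (x$converged) "converged" else "NOT converged",
              x$n_evaluations))
  print(x$transform)
  invisible(x)
}

#' Rigid registration by multi-resolution NMI maximisation
#'
#' Registers a moving (T1w) image to a fixed (PET) image with a
#' derivative-free direction-set optimizer: cyclic 1-D golden-section line
#' searches over the six rigid parameters (scaled 1 mm to 1 degree), run
#' over a three-level resolution pyramid (downsampling factors 4, 2, 1 on
#' the fixed grid) with shrinking search brackets and tolerances.
#' Trilinear interpolation is used throughout. Deterministic given inputs.
#'
#' @param fixed_pet fixed [voxel_grid()] (PET).
#' @param moving_t1w moving [voxel_grid()] (T1w-like).
#' @param init initial [rigid_transform()] (moving world onto fixed world);
#'   default identity.
#' @param bins histogram bins at the finest level (coarser levels use half).
#' @param max_eval evaluation budget per level; exhausting it marks the
#'   result not converged.
#' @return a [registration_result()]; its transform maps moving world
#'   coordinates onto fixed world coordinates.
#' @export
register_rigid <- function(fixed_pet, moving_t1w, init = NULL, bins = 64L,
                           max_eval = 2000L) {
  centre <- grid_centre_world(fixed_pet)
  if (is.null(init)) init <- rigid_transform(centre_mm = centre)
  par <- c(init$translation_mm, init$rotation_deg)

  mov_inv <- solve(moving_t1w$affine)
  n_eval_total <- 0L
  budget_hit <- FALSE

  levels <- list(
    list(factor = 4L, bracket = 12, tol = 0.3, sweeps = 3L,
         bins = bins %/% 2L, max_points = Inf, nm_iter = 0L, fwhm = 0,
         rot_grid = numeric(0)),
    list(factor = 2L, bracket = 6,  tol = 0.1, sweeps = 2L,
         bins = bins %/% 2L, max_points = Inf, nm_iter = 100L, fwhm = 0,
         rot_grid = 2.5 * c(-2:2)),
    list(factor = 1L, bracket = 1.2, tol = 0.02, sweeps = 2L,
         bins = bins, max_points = 18000L, nm_iter = 80L, fwhm = 0,
         rot_grid = 1.5 * c(-2:2))
  )

  last_sim <- NA_real_
  for (lv in levels) {
    fx <- pyramid_level(fixed_pet, lv$factor)
    # Gaussian pyramid: extra smoothing at the coarse levels widens the
    # capture range and merges spurious NMI local optima
    if (lv$fwhm > 0) {
      fx <- smooth_gauss(fx, lv$fwhm)
      mov_arr <- smooth_gauss(moving_t1w, lv$fwhm)$values
    } else {
      mov_arr <- moving_t1w$values
    }
    fvec <- as.vector(fx$values)
    keep <- which(fvec > 0)
    if (length(keep) == 0) next
    # regular subsample of the fixed-voxel set keeps fine-level cost bounded
    if (length(keep) > lv$max_points) {
      stride <- ceiling(length(keep) / lv$max_points)
      keep <- keep[seq(1L, length(keep), by = stride)]
    }
    d <- dim(fx$values)
    idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                                 k = seq_len(d[3]) - 1))[keep, , drop = FALSE]
    wrld <- idx %*% t(fx$affine[1:3, 1:3])
    wrld <- sweep(wrld, 2, fx$affine[1:3, 4], "+")
    fmask <- fvec[keep]
    lbins <- max(8L, lv$bins)
    # bin edges are frozen per level (fixed image over its mask, moving
    # image over its global positive range): evaluating with constant edges
    # keeps the cost surface from jittering as the transform moves
    fr <- range(fmask)
    fb_all <- if (fr[2] > fr[1]) {
      pmin(floor((fmask - fr[1]) / (fr[2] - fr[1]) * lbins), lbins - 1L)
    } else rep(0L, length(fmask))
    mrange <- range(mov_arr[mov_arr > 0])

    n_eval_level <- 0L
    cost <- function(p) {
      n_eval_level <<- n_eval_level + 1L
      tr <- rigid_transform(p[1:3], p[4:6], centre_mm = centre)
      Minv <- mov_inv %*% solve(tr$matrix)
      src <- wrld %*% t(Minv[1:3, 1:3])
      src <- sweep(src, 2, Minv[1:3, 4], "+")
      mv <- interp_trilinear(mov_arr, src, fill = 0)
      ok <- mv > 0
      if (sum(ok) < 32) return(1)   # essentially no overlap: worst score
      mb <- floor((mv[ok] - mrange[1]) / (mrange[2] - mrange[1]) * lbins)
      mb <- pmax(pmin(mb, lbins - 1L), 0L)
      joint <- tabulate(1L + fb_all[ok] + lbins * mb, nbins = lbins * lbins)
      nmi_from_joint(joint, lbins)
    }

    refine <- function(par, cur, sweeps = lv$sweeps, nm_iter = lv$nm_iter) {
      br <- lv$bracket
      for (sw in seq_len(sweeps)) {
        for (pi in 1:6) {
          if (n_eval_level >= max_eval) break
          f1 <- function(v) {
            p <- par; p[pi] <- v
            -cost(p)
          }
          o <- stats::optimize(f1, c(par[pi] - br, par[pi] + br), tol = lv$tol)
          if (-o$objective > cur) {
            par[pi] <- o$minimum
            cur <- -o$objective
          }
        }
        br <- br / 2
        if (n_eval_level >= max_eval) break
      }
      # simplex refinement handles the rotation coupling that axis-wise
      # line searches can get stuck on
      if (nm_iter > 0 && n_eval_level < max_eval) {
        nm <- stats::optim(par, function(p) -cost(p), method = "Nelder-Mead",
                           control = list(maxit = nm_iter, reltol = 1e-7))
        if (-nm$value > cur) {
          par <- nm$par
          cur <- -nm$value
        }
      }
      list(par = par, cur = cur)
    }

    cur <- cost(par)
    if (length(lv$rot_grid) > 0) {
      # deterministic grid scan over coupled rotation offsets: escapes the
      # rotation local optima that axis-wise searches cannot cross; the two
      # best basins are both polished and the winner kept
      offs <- sort(unique(c(0, lv$rot_grid)))
      cand <- expand.grid(ox = offs, oy = offs, oz = offs)
      vals <- numeric(nrow(cand))
      for (ci in seq_len(nrow(cand))) {
        p <- par
        p[4:6] <- p[4:6] + as.numeric(cand[ci, ])
        vals[ci] <- if (all(cand[ci, ] == 0)) cur else cost(p)
      }
      top <- order(vals, decreasing = TRUE)[1:2]
      best <- NULL
      for (k in seq_along(top)) {
        ci <- top[k]
        p <- par
        p[4:6] <- p[4:6] + as.numeric(cand[ci, ])
        # the runner-up basin gets a lighter polish: it only needs to beat
        # the leader if it is the true basin, not to be fully converged
        r <- if (k == 1) refine(p, vals[ci]) else
          refine(p, vals[ci], sweeps = 1L)
        if (is.null(best) || r$cur > best$cur) best <- r
      }
      par <- best$par
      cur <- best$cur
    } else {
      r <- refine(par, cur)
      par <- r$par
      cur <- r$cur
    }
    if (n_eval_level >= max_eval) budget_hit <- TRUE
    last_sim <- cur
    n_eval_total <- n_eval_total + n_eval_level
  }

  registration_result(
    transform = rigid_transform(par[1:3], par[4:6], centre_mm = centre),
    final_similarity = last_sim,
    converged = !budget_hit,
    n_evaluations = n_eval_total
  )
}

#' Propagate a parcellation through a rigid transform
#'
#' Nearest-neighbour resampling of a label volume onto a target grid; the
#' output label set is a subset of the input labels plus 0 (background).
#'
#' @param labels label [voxel_grid()] (integer values).
#' @param transform [rigid_transform()] mapping label world onto target
#'   world, or `NULL` for identity.
#' @param target_grid [voxel_grid()] giving the output geometry.
#' @return label [voxel_grid()] on the target geometry.
#' @export
propagate_labels <- function(labels, transform, target_grid) {
  resample_to_grid(labels, target_grid, transform = transform,
                   method = "nearest", fill = 0L)
}
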